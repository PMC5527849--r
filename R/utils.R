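# Internal helpers: argument checking and deterministic seed substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_input("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stop_input("'%s' must be in [%s, %s]", name, format(lower), format(upper))
  if (integer && x != round(x))
    stop_input("'%s' must be a whole number", name)
  invisible(x)
}

# Derive a 32-bit-safe child seed from a master seed. Used so that each
# generator stage of a synthetic study consumes an independent, reproducible
# random substream.
substream_seed <- function(master, stream) {
  (as.double(master) * 48271 + stream * 7919) %% 2147483647
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
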