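# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Tiny hand-wired network: hub H with partners P1..P5, one extra edge, one
# homodimer.
toy_network <- function() {
  data.frame(
    protein_a = c("H", "H", "H", "H", "H", "P1", "Q"),
    protein_b = c("P1", "P2", "P3", "P4", "P5", "P2", "Q"),
    complex_id = sprintf("C%02d", 1:7),
    up_tag = sprintf("U%02d", 1:7),
    down_tag = sprintf("D%02d", 1:7),
    stringsAsFactors = FALSE
  )
}

# A star network with `n_leaves` leaves around "HUB".
star_network <- function(n_leaves) {
  data.frame(
    protein_a = rep("HUB", n_leaves),
    protein_b = sprintf("L%02d", seq_len(n_leaves)),
    complex_id = sprintf("C%02d", seq_len(n_leaves)),
    up_tag = sprintf("U%02d", seq_len(n_leaves)),
    down_tag = sprintf("D%02d", seq_len(n_leaves)),
    stringsAsFactors = FALSE
  )
}

# Random simple graph on `n` nodes with `m` edges (no self-edges), as an
# edge table.
random_network <- function(n, m, seed) {
  all_pairs <- t(utils::combn(n, 2))
  stopifnot(m <= nrow(all_pairs))
  with_seed_local(seed, {
    idx <- sample.int(nrow(all_pairs), m)
    data.frame(
      protein_a = sprintf("N%03d", all_pairs[idx, 1]),
      protein_b = sprintf("N%03d", all_pairs[idx, 2]),
      complex_id = sprintf("C%04d", seq_len(m)),
      up_tag = sprintf("U%04d", seq_len(m)),
      down_tag = sprintf("D%04d", seq_len(m)),
      stringsAsFactors = FALSE
    )
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Brute-force BH step-up, straight from the definition.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in rev(seq_len(n))) {
    val <- min(prev, n * p[o[k]] / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# Brute-force connected components / density on an edge table (BFS over an
# adjacency list), used as the oracle for dynamic_subgraph.
brute_topology <- function(network, labels, direction) {
  sel <- labels == direction
  if (!any(sel)) return(list(largest_component = 0L, density = 0))
  ea <- network$protein_a[sel]
  eb <- network$protein_b[sel]
  nodes <- unique(c(ea, eb))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(c(eb[ea == v], ea[eb == v])))
  seen <- character(0)
  best <- 0L
  for (v in nodes) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    best <- max(best, length(comp))
  }
  nv <- length(nodes)
  dens <- if (nv >= 2) 2 * sum(sel) / (nv * (nv - 1)) else 0
  list(largest_component = best, density = dens)
}

# Bisection oracle for the mass-action relation Kd = (C1 - C)(C2 - C)/C on
# (0, min(C1, C2)); independent of the closed form under test.
bisect_complex <- function(c1, c2, kd, tol = 1e-13) {
  f <- function(x) (c1 - x) * (c2 - x) / x - kd
  lo <- min(c1, c2) * 1e-12
  hi <- min(c1, c2) * (1 - 1e-15)
  if (f(hi) > 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) / hi < tol) break
  }
  (lo + hi) / 2
}

protein_ids_for_test <- function(n) sprintf("YP%04d", seq_len(n))
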