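# Mass-action prediction of binary protein complex abundance.
#
# Each PCA strain reports one two-protein ("binary") complex. Given resting
# cellular concentrations of the two partners (PaxDB-style ppm units) and a
# dissociation constant, the equilibrium complex concentration follows from
# the law of mass action
#
#   Kd = (C1 - C)(C2 - C) / C
#
# whose physically meaningful root is the closed form implemented in
# `complex_concentration()`. Condition-dependent complex levels are predicted
# by scaling each partner's resting concentration by its mRNA expression
# ratio and re-evaluating the closed form at fixed Kd.

#' Dissociation constant from resting concentrations
#'
#' Models the dissociation constant of a binary complex as proportional to
#' the resting concentration of its more abundant member:
#' `Kd = max(C1, C2) / divisor`. The default divisor of 20 places every
#' complex in a moderately strong binding regime relative to its components.
#'
#' @param c1,c2 Resting concentrations of the two proteins (ppm, > 0).
#'   Vectorized.
#' @param divisor Positive scale factor; larger values approach the tight
#'   binding limit where the complex level equals `min(c1, c2)`.
#' @return Numeric vector of Kd values in the same units as `c1`.
#' @examples
#' assign_kd(100, 200)   # 10
#' assign_kd(50, 50)     # 2.5
#' @export
assign_kd <- function(c1, c2, divisor = 20) {
  if (any(!is.finite(c1)) || any(!is.finite(c2)) || any(c1 <= 0) || any(c2 <= 0))
    stop_input("protein concentrations must be finite and > 0")
  check_number(divisor, "divisor", lower = .Machine$double.eps)
  pmax(c1, c2) / divisor
}

#' Equilibrium concentration of a binary complex
#'
#' Closed-form solution of `Kd = (C1 - C)(C2 - C)/C` for the complex
#' concentration `C`, taking the root satisfying `0 < C <= min(C1, C2)`.
#' Evaluated in the rationalized form
#' `C = 2 C1 C2 / (S + sqrt(S^2 - 4 C1 C2))` with `S = C1 + C2 + Kd`,
#' which is algebraically identical to the quadratic-formula expression but
#' avoids catastrophic cancellation as `Kd -> 0`, where the result tends to
#' `min(C1, C2)`.
#'
#' @param c1,c2 Total concentrations of the two proteins (> 0). Vectorized.
#' @param kd Dissociation constant (>= 0), same units.
#' @return Complex concentration, same units as the inputs.
#' @examples
#' complex_concentration(100, 200, 10)  # 91.557...
#' complex_concentration(100, 200, 0)   # 100 (tight-binding limit)
#' @export
complex_concentration <- function(c1, c2, kd) {
  if (any(!is.finite(c1)) || any(!is.finite(c2)) || any(c1 <= 0) || any(c2 <= 0))
    stop_input("protein concentrations must be finite and > 0")
  if (any(!is.finite(kd)) || any(kd < 0))
    stop_input("kd must be finite and >= 0")
  s <- c1 + c2 + kd
  disc <- s^2 - 4 * c1 * c2
  # disc = (c1 - c2)^2 + kd * (kd + 2*(c1 + c2)) >= 0 for valid inputs;
  # clamp tiny negative round-off.
  if (any(disc < -1e-8 * s^2)) stop("negative discriminant in mass-action root")
  disc[disc < 0] <- 0
  2 * c1 * c2 / (s + sqrt(disc))
}

#' Tight-binding approximation of complex abundance
#'
#' The `Kd -> 0` limit of [complex_concentration()]: the complex level equals
#' the concentration of the less abundant partner.
#'
#' @inheritParams assign_kd
#' @return `pmin(c1, c2)`.
#' @export
min_approximation <- function(c1, c2) {
  if (any(c1 <= 0) || any(c2 <= 0))
    stop_input("protein concentrations must be > 0")
  pmin(c1, c2)
}

#' Barcode-correspondence (tag discordance) filter
#'
#' A strain's UP-tag and DOWN-tag report the same complex; a large gap
#' between their log2 ratios indicates a barcode artifact. Strains with
#' `|log2R_up - log2R_down| > threshold` (strictly) are excluded from
#' model-versus-observation comparisons.
#'
#' @param log2r_up,log2r_down Per-strain tag log2 ratios. Vectorized.
#' @param threshold Maximum tolerated absolute gap (default 1).
#' @return Logical vector, `TRUE` where the strain is retained.
#' @export
discordance_filter <- function(log2r_up, log2r_down, threshold = 1) {
  check_number(threshold, "threshold", lower = 0)
  abs(log2r_up - log2r_down) <= threshold
}

#' Predict condition-dependent complex abundance ratios from mRNA ratios
#'
#' For every edge (binary complex) in the network: the reference complex
#' level is computed from the two resting concentrations and
#' `Kd = max(C1, C2)/divisor`; the condition level is computed after scaling
#' each concentration by its mRNA expression ratio (`R * C`); the prediction
#' is `log2` of the ratio of the two complex levels. Proteins missing from
#' the abundance table fall back to the genomewide median ppm; proteins
#' missing from the expression table use `R = 1` (no change).
#'
#' @param network Edge table with columns `protein_a`, `protein_b`,
#'   `complex_id` (see [generate_network()] / [read_network_tsv()]).
#' @param abundance Data frame with columns `orf` and `ppm` (resting
#'   concentrations, PaxDB convention).
#' @param expression Data frame with column `orf` plus one or more log2-ratio
#'   timepoint columns; `NA` entries are treated as missing.
#' @param timepoint Name of the expression column holding the log2 ratio to
#'   use (default `"t4"`, the 4 h post-shift timepoint).
#' @param divisor Kd divisor passed to [assign_kd()].
#' @param recompute_kd If `TRUE`, Kd is re-derived from the scaled
#'   concentrations in the perturbed condition instead of being held at its
#'   reference value. Default `FALSE`: a binding constant is a property of
#'   the complex, not of the condition.
#' @return Data frame with one row per edge: `complex_id`, `c1`, `c2`, `kd`,
#'   `c_ref`, `c_cond`, `predicted_log2_ratio`, and counts of fallbacks used
#'   as attributes `n_abundance_fallback`, `n_expression_fallback`.
#' @export
predict_complex_ratios <- function(network, abundance, expression,
                                   timepoint = "t4", divisor = 20,
                                   recompute_kd = FALSE) {
  stopifnot(all(c("protein_a", "protein_b", "complex_id") %in% names(network)))
  stopifnot(all(c("orf", "ppm") %in% names(abundance)))
  if (!"orf" %in% names(expression))
    stop_input("expression table must have an 'orf' column")
  if (!timepoint %in% names(expression))
    stop_input("expression table has no timepoint column '%s'", timepoint)

  med <- stats::median(abundance$ppm)
  conc <- function(orf) {
    i <- match(orf, abundance$orf)
    out <- abundance$ppm[i]
    out[is.na(i)] <- med
    out
  }
  ratio <- function(orf) {
    i <- match(orf, expression$orf)
    r <- 2^expression[[timepoint]][i]
    r[is.na(r)] <- 1
    r
  }

  c1 <- conc(network$protein_a)
  c2 <- conc(network$protein_b)
  r1 <- ratio(network$protein_a)
  r2 <- ratio(network$protein_b)

  kd <- assign_kd(c1, c2, divisor)
  c_ref <- complex_concentration(c1, c2, kd)
  kd_cond <- if (recompute_kd) assign_kd(r1 * c1, r2 * c2, divisor) else kd
  c_cond <- complex_concentration(r1 * c1, r2 * c2, kd_cond)

  out <- data.frame(
    complex_id = network$complex_id,
    c1 = c1, c2 = c2, kd = kd,
    c_ref = c_ref, c_cond = c_cond,
    predicted_log2_ratio = log2(c_cond / c_ref),
    stringsAsFactors = FALSE
  )
  attr(out, "n_abundance_fallback") <-
    sum(!c(network$protein_a, network$protein_b) %in% abundance$orf)
  attr(out, "n_expression_fallback") <-
    sum(is.na(match(c(network$protein_a, network$protein_b), expression$orf)) |
          is.na(expression[[timepoint]][match(c(network$protein_a, network$protein_b),
                                              expression$orf)]))
  out
}

#' Direction accuracy of mRNA-based predictions
#'
#' For a grid of minimum predicted effect sizes, computes the fraction of
#' predicted-accumulated complexes that the screen called accumulated, and
#' likewise for depleted, optionally with bootstrap confidence bands.
#'
#' @param predictions Output of [predict_complex_ratios()], optionally
#'   pre-filtered; rows with `included == FALSE` (if present) are dropped.
#' @param calls Call table with columns `complex_id` and `call` (values
#'   `"accumulated"`, `"depleted"`, `"unchanged"`, or exclusion flags).
#' @param bins Numeric vector of minimum `|predicted_log2_ratio|` thresholds.
#' @param among `"all"`: denominator is every prediction passing the bin;
#'   `"significant"`: restrict to complexes called accumulated or depleted,
#'   so the accuracy is the fraction of significant calls whose direction the
#'   model got right (the stratified hub comparison uses this).
#' @param n_boot Bootstrap replicates for 95% confidence bands (0 disables).
#' @param seed Optional seed for the bootstrap.
#' @return Data frame: `min_effect`, `direction`, `n`, `accuracy` (percent),
#'   `ci_lo`, `ci_hi` (`NA` when `n_boot = 0` or the bin is empty).
#' @export
direction_accuracy <- function(predictions, calls, bins = c(0, 0.5, 1, 1.5, 2),
                               among = c("all", "significant"),
                               n_boot = 0, seed = NULL) {
  among <- match.arg(among)
  if ("included" %in% names(predictions))
    predictions <- predictions[predictions$included, , drop = FALSE]
  m <- merge(predictions[, c("complex_id", "predicted_log2_ratio")],
             calls[, c("complex_id", "call")], by = "complex_id")
  if (among == "significant")
    m <- m[m$call %in% c("accumulated", "depleted"), , drop = FALSE]

  one_acc <- function(dat, bin, dir) {
    sel <- abs(dat$predicted_log2_ratio) >= bin &
      (if (dir == "accumulated") dat$predicted_log2_ratio > 0
       else dat$predicted_log2_ratio < 0)
    d <- dat[sel, , drop = FALSE]
    if (nrow(d) == 0) return(c(n = 0, acc = NA_real_))
    c(n = nrow(d), acc = 100 * mean(d$call == dir))
  }

  run <- function(dat) {
    do.call(rbind, lapply(bins, function(b) {
      do.call(rbind, lapply(c("accumulated", "depleted"), function(dir) {
        v <- one_acc(dat, b, dir)
        data.frame(min_effect = b, direction = dir, n = v["n"],
                   accuracy = v["acc"], row.names = NULL)
      }))
    }))
  }

  out <- run(m)
  out$ci_lo <- NA_real_
  out$ci_hi <- NA_real_
  if (n_boot > 0 && nrow(m) > 0) {
    boot_fun <- function() {
      idx <- sample.int(nrow(m), replace = TRUE)
      run(m[idx, , drop = FALSE])$accuracy
    }
    boots <- if (is.null(seed)) replicate(n_boot, boot_fun())
             else with_seed(seed, replicate(n_boot, boot_fun()))
    boots <- matrix(boots, ncol = n_boot)
    out$ci_lo <- apply(boots, 1, stats::quantile, probs = 0.025, na.rm = TRUE,
                       names = FALSE)
    out$ci_hi <- apply(boots, 1, stats::quantile, probs = 0.975, na.rm = TRUE,
                       names = FALSE)
  }
  rownames(out) <- NULL
  out
}
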