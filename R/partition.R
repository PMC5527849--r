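# Measurement-error-corrected variance partitioning.
#
# An observed model-to-data correlation understates the model's intrinsic
# explanatory power because both the expression input and the barcode
# readout are noisy (attenuation). For two equally noisy measurements of an
# ideal signal X,  rho(X+e1, X+e2) = sigma_X^2 / (sigma_X^2 + sigma_e^2),
# so the noise magnitude reproducing an observed replicate correlation rho
# is  sigma_e = sigma_X * sqrt(1/rho - 1).  "Noise-added" replicates —
# perfect model predictions degraded by exactly that much noise — bound the
# correlation any model could achieve; comparing the realized model-to-data
# correlation against that bound isolates the intrinsic model error:
#
#   rho_mod^2 = 1 / (1/rho_total^2 - 1/rho_exp^2 + 1).

#' Noise standard deviation reproducing a replicate correlation
#'
#' `sigma_eps = sigma_x * sqrt(1/rho - 1)`: the standard deviation of
#' independent Gaussian noise that, added to a signal of spread `sigma_x`,
#' makes two replicates correlate at `rho`.
#'
#' @param sigma_x Standard deviation of the underlying signal (log2 scale).
#' @param rho Observed correlation between two replicates, in (0, 1].
#' @return The noise standard deviation (0 when `rho = 1`).
#' @export
sigma_from_correlation <- function(sigma_x, rho) {
  check_number(sigma_x, "sigma_x", lower = 0)
  if (!is.numeric(rho) || any(rho <= 0) || any(rho > 1))
    stop_input("rho must lie in (0, 1]")
  sigma_x * sqrt(1 / rho - 1)
}

#' Bundle the replicate correlations defining the noise model
#'
#' @param rho_rep Correlation between replicate expression measurements
#'   (noise added to the model input).
#' @param rho_bio Correlation between biological replicates of the barcode
#'   readout (same tag, different replicate).
#' @param rho_tag Correlation between the two tags of the same strain
#'   within a replicate.
#' @return A list of class `"bcpca_noise"`.
#' @export
noise_model <- function(rho_rep = 1, rho_bio = 1, rho_tag = 1) {
  for (r in c(rho_rep, rho_bio, rho_tag))
    if (r <= 0 || r > 1) stop_input("correlations must lie in (0, 1]")
  structure(list(rho_rep = rho_rep, rho_bio = rho_bio, rho_tag = rho_tag),
            class = "bcpca_noise")
}

#' Generate one noise-added replicate of the barcode readout
#'
#' Three steps: (i) Gaussian noise calibrated to the expression replicate
#' correlation is added to the log2 expression ratios; (ii) the mass-action
#' model maps the noisy expression through to predicted complex log2
#' ratios; (iii) two independent Gaussian terms calibrated to the
#' biological-replicate and tag correlations are added to the output. The
#' reference spread `sigma_x` for each step is the standard deviation of
#' the corresponding reference vector (input ratios for step i, predicted
#' ratios for step iii).
#'
#' @param expression Expression table (`orf` plus timepoint columns).
#' @param network,abundance As in [predict_complex_ratios()].
#' @param noise A [noise_model()].
#' @param timepoint Expression column to perturb and use.
#' @param divisor Kd divisor.
#' @return Numeric vector of simulated complex log2 ratios, named by
#'   `complex_id`.
#' @export
make_noise_added_replicate <- function(expression, network, abundance, noise,
                                       timepoint = "t4", divisor = 20) {
  stopifnot(inherits(noise, "bcpca_noise"))
  ex <- expression
  vals <- ex[[timepoint]]
  sigma_in <- sigma_from_correlation(stats::sd(vals, na.rm = TRUE),
                                     noise$rho_rep)
  ok <- !is.na(vals)
  ex[[timepoint]][ok] <- vals[ok] + stats::rnorm(sum(ok), 0, sigma_in)

  pred <- predict_complex_ratios(network, abundance = abundance,
                                 expression = ex,
                                 timepoint = timepoint, divisor = divisor)
  y <- pred$predicted_log2_ratio
  sigma_y <- stats::sd(y)
  y <- y + stats::rnorm(length(y), 0, sigma_from_correlation(sigma_y, noise$rho_bio)) +
           stats::rnorm(length(y), 0, sigma_from_correlation(sigma_y, noise$rho_tag))
  stats::setNames(y, pred$complex_id)
}

#' Experimental-ceiling estimates from noise-added replicate pairs
#'
#' For two equally noisy replicates of the same signal,
#' `rho(X+e1, X+e2) = sigma_X^2 / (sigma_X^2 + sigma_e^2) = rho(X, X+e)^2`:
#' the *unsquared* correlation between a replicate pair is already an
#' estimate of the squared signal-versus-noisy-measurement correlation,
#' i.e. of the variance-explained ceiling `rho_exp^2` that experimental
#' error alone imposes. One estimate per unordered pair: `n(n-1)/2` values.
#'
#' @param replicates Numeric matrix with one column per replicate (or a
#'   list of equal-length vectors).
#' @return Vector of `rho_exp^2` estimates, one per unordered replicate
#'   pair. Pairs involving a constant replicate are skipped with a warning.
#' @export
pairwise_rho_exp <- function(replicates) {
  if (is.list(replicates)) replicates <- do.call(cbind, replicates)
  n <- ncol(replicates)
  if (n < 2) stop_input("need at least two replicates")
  sds <- apply(replicates, 2, stats::sd)
  if (any(sds == 0))
    warning("constant replicate(s); their pairs are skipped")
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (sds[i] == 0 || sds[j] == 0) next
      out <- c(out, stats::cor(replicates[, i], replicates[, j]))
    }
  }
  out
}

#' Intrinsic model variance explained after noise correction
#'
#' `rho_mod^2 = 1 / (1/rho_total^2 - 1/rho_exp^2 + 1)`, where `rho_total^2`
#' is the squared correlation of the model prediction with the observation
#' and `rho_exp^2` the squared correlation between noise-added replicates
#' (the ceiling imposed by experimental error alone). Inputs outside the
#' admissible ordering `0 < rho_total^2 <= rho_exp^2 <= 1` are clipped with
#' a warning; `rho_total^2 = 0` yields `NA`.
#'
#' @param rho_total_sq,rho_exp_sq Squared correlations. Vectorized.
#' @return The intrinsic variance-explained estimate(s) in \[0, 1\].
#' @export
intrinsic_rho_mod_sq <- function(rho_total_sq, rho_exp_sq) {
  n <- max(length(rho_total_sq), length(rho_exp_sq))
  rho_total_sq <- rep_len(rho_total_sq, n)
  rho_exp_sq <- rep_len(rho_exp_sq, n)
  if (any(rho_exp_sq <= 0 | rho_exp_sq > 1, na.rm = TRUE))
    stop_input("rho_exp_sq must lie in (0, 1]")
  bad <- !is.na(rho_total_sq) & rho_total_sq > rho_exp_sq
  if (any(bad)) {
    warning("rho_total_sq > rho_exp_sq; clipped to the experimental ceiling")
    rho_total_sq[bad] <- rho_exp_sq[bad]
  }
  out <- 1 / (1 / rho_total_sq - 1 / rho_exp_sq + 1)
  out[!is.na(rho_total_sq) & rho_total_sq == 0] <- NA_real_
  out
}

#' Distribution of intrinsic variance-explained estimates
#'
#' Simulates `n_replicates` noise-added datasets, forms all pairwise
#' `rho_exp^2` samples, pairs each with a bootstrap-resampled `rho_total^2`
#' (observed model-to-data squared correlation over resampled complexes),
#' and converts each pair through [intrinsic_rho_mod_sq()].
#'
#' @param predictions Output of [predict_complex_ratios()] on the observed
#'   expression data.
#' @param observed Data frame with columns `complex_id` and `log2r`
#'   (observed complex log2 ratios, e.g. the conservative or tag-averaged
#'   screen values).
#' @param expression,network,abundance,noise,timepoint,divisor Passed to
#'   [make_noise_added_replicate()].
#' @param n_replicates Number of noise-added replicates (default 100,
#'   giving `choose(100, 2) = 4950` pairwise estimates).
#' @param significant_only Optional character vector of complex ids to
#'   restrict the comparison to (e.g. significantly dynamic complexes).
#' @param seed Optional seed.
#' @return List of class `"bcpca_partition"`: `samples` (data frame with
#'   `rho_exp_sq`, `rho_total_sq`, `rho_mod_sq`), `rho_total_sq` (point
#'   estimate), `median`, `p5`, `p95`, `n_complexes`.
#' @export
partition_distribution <- function(predictions, observed, expression, network,
                                   abundance, noise, timepoint = "t4",
                                   divisor = 20, n_replicates = 100,
                                   significant_only = NULL, seed = NULL) {
  m <- merge(predictions[, c("complex_id", "predicted_log2_ratio")],
             observed[, c("complex_id", "log2r")], by = "complex_id")
  if (!is.null(significant_only))
    m <- m[m$complex_id %in% significant_only, , drop = FALSE]
  if (nrow(m) < 10)
    stop_input("fewer than 10 aligned complexes (%d)", nrow(m))

  run <- function() {
    reps <- replicate(n_replicates,
      make_noise_added_replicate(expression, network, abundance, noise,
                                 timepoint = timepoint, divisor = divisor))
    reps <- reps[match(m$complex_id, rownames(reps)), , drop = FALSE]
    rho_exp_sq <- pairwise_rho_exp(reps)
    rho_total_sq <- vapply(seq_along(rho_exp_sq), function(i) {
      idx <- sample.int(nrow(m), replace = TRUE)
      stats::cor(m$predicted_log2_ratio[idx], m$log2r[idx])^2
    }, numeric(1))
    data.frame(rho_exp_sq = rho_exp_sq, rho_total_sq = rho_total_sq,
               rho_mod_sq = intrinsic_rho_mod_sq(rho_total_sq, rho_exp_sq))
  }
  samples <- if (is.null(seed)) run() else with_seed(seed, run())

  est <- samples$rho_mod_sq[!is.na(samples$rho_mod_sq)]
  structure(list(
    samples = samples,
    rho_total_sq = stats::cor(m$predicted_log2_ratio, m$log2r)^2,
    median = stats::median(est),
    p5 = stats::quantile(est, 0.05, names = FALSE),
    p95 = stats::quantile(est, 0.95, names = FALSE),
    n_complexes = nrow(m)
  ), class = "bcpca_partition")
}

#' @export
print.bcpca_partition <- function(x, ...) {
  cat(sprintf(
    "bcpca_partition: %d complexes, %d estimates\n  rho_total^2 = %.3f; intrinsic rho_mod^2 median = %.3f [%.3f, %.3f]\n",
    x$n_complexes, nrow(x$samples), x$rho_total_sq, x$median, x$p5, x$p95))
  invisible(x)
}
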