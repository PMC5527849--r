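# Empirical-Bayes moderated two-group t-statistic.
#
# Residual variances across tags are shrunk toward a common prior value
# s0^2 with d0 prior degrees of freedom, fitted by moment matching on the
# log residual variances (the scaled-F hierarchical model of Smyth 2004).
# The moderated statistic uses the posterior variance
#   s~^2 = (d0 s0^2 + dg sg^2) / (d0 + dg)
# and is referred to a t distribution on d0 + dg degrees of freedom.

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  if (!is.finite(x)) return(if (x > 0) 0 else Inf)
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Fit the variance-shrinkage hyperparameters (d0, s0^2)
#'
#' Moment matching on `z = log(s^2)`: under the hierarchical model,
#' `e = z - digamma(dg/2) + log(dg/2)` has mean
#' `log(s0^2) - digamma(d0/2) + log(d0/2)` and variance
#' `trigamma(dg/2) + trigamma(d0/2)`, so `d0` is recovered by inverting the
#' trigamma function on the excess spread of `e` and `s0^2` from its mean.
#' Variances numerically indistinguishable from zero are excluded from the
#' fit. When the observed spread does not exceed the sampling spread, `d0`
#' is infinite (complete shrinkage).
#'
#' @param s2 Residual variances, one per tag.
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List with elements `d0` and `s02`.
#' @keywords internal
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 1e-12 & df > 0
  if (sum(ok) < 2)
    return(list(d0 = 0, s02 = if (any(ok)) mean(s2[ok]) else 0))
  z <- log(s2[ok])
  dg <- df[ok]
  e <- z - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2 * n / (n - 1)) - mean(trigamma(dg / 2))
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: complete shrinkage, and the
    # moment estimator of the common variance is the plain mean
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group t-test for a matrix of tags
#'
#' Row-wise two-sample contrast (treatment mean minus control mean) with an
#' empirical-Bayes-shrunken pooled variance. Hyperparameters are fitted by
#' [fit_variance_prior()] across all rows supplied, so rows should form one
#' tag class (UP or DOWN) as they are normalized and amplified together.
#'
#' Degenerate variances are handled explicitly: when the posterior standard
#' deviation of a row is zero, the statistic is `0` (p = 1) for a zero
#' contrast and signed infinity (p = 0) otherwise.
#'
#' @param mat Numeric matrix, rows = tags, columns = arrays, values on the
#'   log2 scale.
#' @param treatment Column indices (or logical) of the treatment group.
#' @param control Column indices (or logical) of the control group.
#' @param d0_override Optional forced prior degrees of freedom: `0` gives
#'   the ordinary pooled t, `Inf` fully shrinks every variance to `s0^2`.
#' @return Data frame: `log2r` (contrast), `t`, `p`, `df_residual`,
#'   `df_prior` (same for all rows), `s2_post`.
#' @export
moderated_t <- function(mat, treatment, control, d0_override = NULL) {
  mat <- as.matrix(mat)
  x1 <- mat[, treatment, drop = FALSE]
  x2 <- mat[, control, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2)
    stop_input("need >= 2 replicates in each group (got %d and %d)", n1, n2)

  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- rss / dg

  prior <- fit_variance_prior(s2, dg)
  d0 <- d0_override %||% prior$d0
  s02 <- prior$s02
  check_number(d0, "d0_override", lower = 0)

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + dg * s2) / (d0 + dg)
  df_total <- if (is.infinite(d0)) Inf else d0 + dg

  diff <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, diff / se,
              ifelse(abs(diff) > 0, sign(diff) * Inf, 0))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df = df_total), 0)

  data.frame(log2r = diff, t = t, p = p,
             df_residual = dg, df_prior = d0, s2_post = s2_post,
             row.names = rownames(mat), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts p-values to q-values controlling the false discovery rate.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, monotone in `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
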