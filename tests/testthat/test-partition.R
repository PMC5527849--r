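# Attenuation algebra and the noise-added replicate machinery.

test_that("sigma_from_correlation inverts the attenuation identity", {
  expect_equal(sigma_from_correlation(2, 0.5), 2)
  expect_equal(sigma_from_correlation(1, 0.8), 0.5)
  expect_equal(sigma_from_correlation(1, 1), 0)
  expect_error(sigma_from_correlation(1, 0), "\\(0, 1\\]")
  # empirical attenuation identity: with noise calibrated to a replicate
  # correlation of rho, rho(X, X+e)^2 = sigma_x^2/(sigma_x^2+sigma_e^2) = rho
  set.seed(51)
  n <- 1e5
  x <- rnorm(n, sd = 2)
  rho_target <- 0.7
  sig <- sigma_from_correlation(2, rho_target)
  e1 <- rnorm(n, sd = sig)
  e2 <- rnorm(n, sd = sig)
  expect_equal(cor(x, x + e1)^2, rho_target, tolerance = 0.01)
  expect_equal(cor(x + e1, x + e2), rho_target, tolerance = 0.01)
  expect_equal(cor(x, x + e1)^2, 2^2 / (2^2 + sd(e1)^2), tolerance = 0.01)
})

test_that("replicate-pair correlations estimate the squared signal correlation", {
  set.seed(52)
  n <- 2e4
  x <- rnorm(n)
  sig <- sigma_from_correlation(1, 0.8)
  r1 <- x + rnorm(n, sd = sig)
  r2 <- x + rnorm(n, sd = sig)
  # the unsquared pair correlation equals the squared signal correlation
  expect_equal(cor(r1, r2), cor(x, r1)^2, tolerance = 0.02)
  expect_equal(pairwise_rho_exp(cbind(r1, r2)), cor(r1, r2))
})

test_that("pairwise_rho_exp returns n(n-1)/2 estimates and handles degenerate input", {
  set.seed(53)
  reps <- matrix(rnorm(50 * 10), ncol = 10)
  expect_length(pairwise_rho_exp(reps), 45)
  expect_length(pairwise_rho_exp(reps[, 1:2]), 1)
  noiseless <- matrix(rep(rnorm(20), 3), ncol = 3)
  expect_equal(pairwise_rho_exp(noiseless), rep(1, 3))
  const <- cbind(rnorm(20), rep(1, 20), rnorm(20))
  expect_warning(out <- pairwise_rho_exp(const), "constant")
  expect_length(out, 1)
  expect_error(pairwise_rho_exp(matrix(1:5, ncol = 1)), "two replicates")
})

test_that("intrinsic rho_mod^2 follows the printed partition formula", {
  expect_equal(intrinsic_rho_mod_sq(0.3, 1), 0.3)
  expect_equal(intrinsic_rho_mod_sq(0.5, 0.5), 1)
  expect_equal(intrinsic_rho_mod_sq(0.25, 0.5), 1 / 3)
  expect_warning(out <- intrinsic_rho_mod_sq(0.9, 0.5), "clipped")
  expect_equal(out, 1)
  expect_true(is.na(suppressWarnings(intrinsic_rho_mod_sq(0, 0.5))))
  # scale invariance of the whole estimate: correlations are unitless
  set.seed(54)
  x <- rnorm(500); y <- x + rnorm(500)
  expect_equal(intrinsic_rho_mod_sq(cor(10 * x, 10 * y)^2, 0.9),
               intrinsic_rho_mod_sq(cor(x, y)^2, 0.9))
})

test_that("noise-added replicates are deterministic under a fixed seed and exact when noiseless", {
  s <- synthetic_spec(n_proteins = 80, n_interactions = 150, hub_count = 2,
                      n_node_effects = 10, expression_noise_sd = 0, seed = 55)
  st <- simulate_study(s)
  quiet <- noise_model(1, 1, 1)
  r0 <- with_seed_local(56, make_noise_added_replicate(
    st$expression, st$network, st$abundance, quiet))
  pred <- predict_complex_ratios(st$network, st$abundance, st$expression)
  expect_equal(unname(r0), pred$predicted_log2_ratio)
  noisy <- noise_model(0.95, 0.9, 0.9)
  ra <- with_seed_local(57, make_noise_added_replicate(
    st$expression, st$network, st$abundance, noisy))
  rb <- with_seed_local(57, make_noise_added_replicate(
    st$expression, st$network, st$abundance, noisy))
  expect_identical(ra, rb)
  expect_false(isTRUE(all.equal(unname(ra), pred$predicted_log2_ratio)))
})

test_that("partition distribution recovers an injected intrinsic rho_mod^2", {
  s <- synthetic_spec(n_proteins = 300, n_interactions = 600, hub_count = 6,
                      n_node_effects = 40, edge_effect_count = 0,
                      expression_noise_sd = 0, seed = 58)
  st <- simulate_study(s)
  pred <- predict_complex_ratios(st$network, st$abundance, st$expression)
  p <- pred$predicted_log2_ratio
  sx <- sd(p)
  rho_bio <- 0.9; rho_tag <- 0.9
  obs <- with_seed_local(59,
    p + rnorm(length(p), 0, sigma_from_correlation(sx, 0.6)) +
      rnorm(length(p), 0, sigma_from_correlation(sx, rho_bio)) +
      rnorm(length(p), 0, sigma_from_correlation(sx, rho_tag)))
  observed <- data.frame(complex_id = pred$complex_id, log2r = obs)
  part <- partition_distribution(pred, observed, st$expression, st$network,
                                 st$abundance,
                                 noise_model(1, rho_bio, rho_tag),
                                 n_replicates = 40, seed = 60)
  expect_equal(nrow(part$samples), choose(40, 2))
  expect_gt(part$median, 0.5)
  expect_lt(part$median, 0.72)
  # with no model error the estimate approaches 1
  obs2 <- with_seed_local(61,
    p + rnorm(length(p), 0, sigma_from_correlation(sx, rho_bio)) +
      rnorm(length(p), 0, sigma_from_correlation(sx, rho_tag)))
  part2 <- suppressWarnings(partition_distribution(pred,
                                  data.frame(complex_id = pred$complex_id,
                                             log2r = obs2),
                                  st$expression, st$network, st$abundance,
                                  noise_model(1, rho_bio, rho_tag),
                                  n_replicates = 40, seed = 62))
  expect_gt(part2$median, 0.9)
})
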