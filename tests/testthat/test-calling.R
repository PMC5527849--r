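# Quantile normalization, dual-tag calling, exclusion rules, and the small
# growth/qPCR formulas.

tiny_intensity <- function(values, n_complex, cols) {
  rows <- data.frame(complex_id = rep(sprintf("C%02d", seq_len(n_complex)), 2),
                     tag = rep(c("UP", "DOWN"), each = n_complex))
  pca_intensity(values, rows, cols)
}

test_that("quantile normalization maps columns onto per-rank means within a tag class", {
  # UP rows carry the worked example [1,2,3] vs [2,4,6]; DOWN rows are
  # constant so any leakage across classes would show.
  vals <- rbind(cbind(c(1, 2, 3), c(2, 4, 6)),
                cbind(c(7, 7, 7), c(7, 7, 7)))
  cols <- data.frame(condition = c("a", "b"), replicate = c(1L, 1L),
                     selection = "plusMTX")
  x <- tiny_intensity(vals, 3, cols)
  nx <- quantile_normalize(x)
  expect_equal(nx$values[1:3, 1], log2(c(1.5, 3, 4.5)))
  expect_equal(nx$values[1:3, 2], log2(c(1.5, 3, 4.5)))
  expect_equal(nx$values[4:6, ], matrix(log2(7), 3, 2), ignore_attr = TRUE)
  expect_true(nx$normalized && nx$log2)
  # identical columns are only log2-transformed
  same <- tiny_intensity(rbind(cbind(1:3, 1:3), cbind(4:6, 4:6)), 3, cols)
  ns <- quantile_normalize(same)
  expect_equal(ns$values[1:3, 1], log2(1:3))
  # after normalization the sorted value multiset is column-invariant
  expect_equal(sort(nx$values[1:3, 1]), sort(nx$values[1:3, 2]))
})

test_that("permuting one tag class leaves the other class untouched", {
  set.seed(8)
  vals <- matrix(10^runif(40, 1, 3), nrow = 8)
  cols <- data.frame(condition = "a", replicate = 1:5, selection = "plusMTX")
  x <- tiny_intensity(vals, 4, cols)
  n1 <- quantile_normalize(x)
  x2 <- x
  x2$values[1:4, ] <- x$values[1:4, sample(5)] # shuffle UP columns' content
  n2 <- quantile_normalize(x2)
  expect_equal(n1$values[5:8, ], n2$values[5:8, ])
})

test_that("log ratios are treatment mean minus control mean per tag", {
  vals <- 2^rbind(c(5, 5, 4, 4, 4, 4, 4, 4),
                  c(6, 6, 6, 6, 6, 6, 6, 6))
  cols <- data.frame(condition = c("trt", "trt", rep("ctl", 6)),
                     replicate = c(1:2, 1:6), selection = "plusMTX")
  x <- tiny_intensity(vals, 1, cols)
  x$values <- log2(x$values); x$log2 <- TRUE
  lr <- compute_log_ratios(x, "trt", "ctl")
  expect_equal(lr$log2r, c(1, 0))
  expect_error(compute_log_ratios(x, "nope", "ctl"), "not found")
})

test_that("dual-tag thresholds are strict and require matching signs", {
  base <- data.frame(
    complex_id = rep(c("A", "B", "C", "D"), 2),
    tag = rep(c("UP", "DOWN"), each = 4),
    log2r = c(0.3, 0.25, 0.3, -0.3, 0.26, 0.4, -0.3, -0.26),
    q = c(0.01, 0.01, 0.01, 0.04, 0.04, 0.01, 0.01, 0.01))
  calls <- call_complexes(base)
  got <- setNames(calls$call, calls$complex_id)
  expect_equal(unname(got["A"]), "accumulated") # 0.3/0.26, q 0.01/0.04
  expect_equal(unname(got["B"]), "unchanged")   # up log2r = 0.25 exactly
  expect_equal(unname(got["C"]), "unchanged")   # opposite signs
  expect_equal(unname(got["D"]), "depleted")
})

test_that("-MTX exclusions and fragment association propagate", {
  net <- data.frame(
    protein_a = c("HNM1", "HNM1", "HNM1", "X", "Y"),
    protein_b = c("A", "B", "C", "A", "B"),
    complex_id = sprintf("C%d", 1:5),
    up_tag = sprintf("U%d", 1:5), down_tag = sprintf("D%d", 1:5))
  # C1 and C2 (both carrying HNM1-F12) show -MTX effects: the fragment
  # recurs, so C3 is excluded by association; C4/C5 are untouched.
  minus_calls <- data.frame(complex_id = sprintf("C%d", 1:5),
                            call = c("depleted", "depleted", "unchanged",
                                     "unchanged", "unchanged"))
  direct <- identify_tag_effects(minus_calls)
  expect_equal(direct, c("C1", "C2"))
  expect_equal(exclude_by_association(direct, net), "C3")
  # a fragment occurring exactly once does not extend
  expect_equal(exclude_by_association("C4", net), character(0))
  expect_equal(exclude_by_association(character(0), net), character(0))
})

test_that("excluded complexes are never called accumulated or depleted", {
  s <- synthetic_spec(n_proteins = 60, n_interactions = 100, hub_count = 2,
                      n_node_effects = 6, edge_effect_count = 4,
                      protein_fold_change_range = c(0.6, 2), seed = 31)
  # plant selection-independent fitness effects on mid-abundance strains
  # (quantile normalization compresses shifts at the distribution edges)
  truth0 <- generate_condition_state(generate_network(s),
                                     generate_abundances(s), s)
  mid <- order(abs(rank(truth0$edges$c_ref) - nrow(truth0$edges) / 2))[1:2]
  affected <- truth0$edges$complex_id[mid]
  fit_shift <- setNames(c(1.2, -1.2), affected)
  study <- simulate_study(s, tag_fitness = fit_shift)
  calls <- bcpca_calls(study$intensities, study$network, "treatment")
  expect_true(all(affected %in%
                    calls$complex_id[grepl("excluded", calls$call)]))
  expect_false(any(calls$call[grepl("excluded", calls$call)] %in%
                     c("accumulated", "depleted")))
})

test_that("call-frequency summary counts dynamic complexes per condition", {
  calls <- data.frame(
    complex_id = c("A", "A", "A", "A", "B", "C"),
    condition = c("c1", "c2", "c3", "c4", "c1", "c1"),
    call = c(rep("accumulated", 4), "depleted", "unchanged"))
  s <- summarize_call_table(calls, min_changes = 2)
  expect_equal(unname(s["dynamic"]), 2)
  expect_equal(unname(s["dynamic_1_3"]), 1)
  expect_equal(unname(s["dynamic_4_plus"]), 1)
  expect_equal(unname(s["conditions_ge_min"]), 1) # c1 has 2 dynamic calls
})

test_that("growth AUC and relative growth follow the baseline-zeroed sums", {
  expect_equal(growth_auc(rep(0.3, 20)), 0)
  expect_equal(growth_auc(c(rep(0, 10), 0.1, 0.2)), 0.3)
  expect_error(growth_auc(1:5), "at least 10")
  expect_equal(relative_growth(12, 12), 0)
  expect_equal(relative_growth(18, 12), 0.5)
})

test_that("qPCR ratios follow the delta-delta-Ct formula", {
  expect_equal(qpcr_ratio(10, 10, 12, 12), 1)       # dCt equal
  expect_equal(qpcr_ratio(13, 10, 12, 12), 0.125)   # 3-cycle shift, 8-fold down
  expect_equal(qpcr_ratio(9, 10, 12, 12), 2)
})
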