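# Differential complex calling from pooled barcode intensities.
#
# Every PCA strain carries two independent barcodes (UP-tag and DOWN-tag)
# whose array fluorescence reports the strain's abundance after competitive
# growth. Raw intensities are quantile-normalized within each tag class,
# log2-transformed, contrasted (treatment mean minus control mean), tested
# with the moderated t, BH-adjusted, and thresholded with the dual-tag rule:
# a complex is accumulated/depleted only when BOTH tags pass the effect-size
# and significance cutoffs in the same direction. Strains with a growth
# response in non-selective (-MTX) media are tag artifacts and are excluded,
# together with all strains sharing a recurrently artifactual PCA fragment.

#' Construct a barcode intensity matrix
#'
#' @param values Numeric matrix, one row per tag, one column per array.
#'   Raw fluorescence (linear scale, > 0) unless `log2 = TRUE`.
#' @param rows Data frame describing rows: columns `complex_id` and `tag`
#'   (`"UP"` or `"DOWN"`). Every complex must contribute exactly one row of
#'   each tag class.
#' @param cols Data frame describing columns: `condition`, `replicate`,
#'   `selection` (`"plusMTX"` or `"minusMTX"`).
#' @param log2 Whether `values` are already log2-transformed.
#' @param normalized Whether quantile normalization has been applied.
#' @return An object of class `"pca_intensity"`.
#' @export
pca_intensity <- function(values, rows, cols, log2 = FALSE, normalized = FALSE) {
  values <- as.matrix(values)
  stopifnot(all(c("complex_id", "tag") %in% names(rows)),
            all(c("condition", "replicate", "selection") %in% names(cols)))
  if (nrow(rows) != nrow(values) || nrow(cols) != ncol(values))
    stop_input("row/column metadata do not match the matrix dimensions")
  if (!all(rows$tag %in% c("UP", "DOWN")))
    stop_input("tag must be 'UP' or 'DOWN'")
  if (!all(cols$selection %in% c("plusMTX", "minusMTX")))
    stop_input("selection must be 'plusMTX' or 'minusMTX'")
  if (anyNA(values))
    stop_input("intensity matrix contains missing cells")
  if (!log2 && any(values <= 0))
    stop_input("raw intensities must be strictly positive")
  tab <- table(rows$complex_id, rows$tag)
  if (!all(tab == 1))
    stop_input("every complex needs exactly one UP and one DOWN row")
  structure(list(values = values, rows = rows, cols = cols,
                 log2 = log2, normalized = normalized),
            class = "pca_intensity")
}

#' @export
print.pca_intensity <- function(x, ...) {
  cat(sprintf("pca_intensity: %d tags (%d complexes) x %d arrays [%s%s]\n",
              nrow(x$values), nrow(x$values) / 2L, ncol(x$values),
              if (x$log2) "log2" else "raw",
              if (x$normalized) ", quantile-normalized" else ""))
  invisible(x)
}

#' Quantile-normalize barcode intensities within tag classes
#'
#' Raw fluorescence is quantile-normalized (each column mapped onto the
#' per-rank cross-column means; ties receive the mean of the rank means they
#' span) and then log2-transformed. Normalization is performed separately
#' for UP-tag and DOWN-tag rows because the two tag pools are PCR-amplified
#' separately, and separately within each selection regime, whose intensity
#' distributions differ.
#'
#' @param x A raw `"pca_intensity"` object.
#' @return The object with normalized, log2-scale values.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "pca_intensity"))
  if (x$normalized) stop_input("intensities are already normalized")
  if (x$log2) stop_input("quantile normalization expects raw intensities")
  v <- x$values
  for (tag in c("UP", "DOWN")) {
    for (sel in unique(x$cols$selection)) {
      r <- x$rows$tag == tag
      cc <- x$cols$selection == sel
      if (sum(cc) < 2) stop_input("need >= 2 columns per tag class to normalize")
      v[r, cc] <- limma::normalizeQuantiles(v[r, cc, drop = FALSE])
    }
  }
  x$values <- log2(v)
  x$log2 <- TRUE
  x$normalized <- TRUE
  x
}

# Column selector helper.
which_cols <- function(x, condition, selection) {
  which(x$cols$condition == condition & x$cols$selection == selection)
}

#' Per-tag log2 ratios of a condition against the control
#'
#' `log2R = mean(log2 treatment columns) - mean(log2 control columns)`,
#' computed separately for UP- and DOWN-tag rows.
#'
#' @param x A log2-scale `"pca_intensity"` object.
#' @param condition Treatment condition label.
#' @param control Control condition label.
#' @param selection Which selection regime's arrays to contrast.
#' @return Data frame: `complex_id`, `tag`, `log2r`.
#' @export
compute_log_ratios <- function(x, condition, control = "control",
                               selection = "plusMTX") {
  stopifnot(inherits(x, "pca_intensity"))
  if (!x$log2) stop_input("intensities must be on the log2 scale")
  tr <- which_cols(x, condition, selection)
  ct <- which_cols(x, control, selection)
  if (length(tr) == 0) stop_input("condition '%s' not found", condition)
  if (length(ct) == 0) stop_input("control '%s' not found", control)
  data.frame(complex_id = x$rows$complex_id, tag = x$rows$tag,
             log2r = rowMeans(x$values[, tr, drop = FALSE]) -
                     rowMeans(x$values[, ct, drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Per-tag moderated-t statistics for one condition contrast
#'
#' Runs [moderated_t()] separately within each tag class (hyperparameters
#' are shared only among tags that were amplified and normalized together)
#' and BH-adjusts the p-values within each class.
#'
#' @inheritParams compute_log_ratios
#' @return Data frame: `complex_id`, `tag`, `log2r`, `t`, `p`, `q`.
#' @export
tag_statistics <- function(x, condition, control = "control",
                           selection = "plusMTX") {
  stopifnot(inherits(x, "pca_intensity"))
  if (!x$log2) stop_input("intensities must be on the log2 scale")
  tr <- which_cols(x, condition, selection)
  ct <- which_cols(x, control, selection)
  if (length(tr) == 0) stop_input("condition '%s' not found", condition)
  out <- lapply(c("UP", "DOWN"), function(tag) {
    r <- x$rows$tag == tag
    fit <- moderated_t(x$values[r, , drop = FALSE], tr, ct)
    data.frame(complex_id = x$rows$complex_id[r], tag = tag,
               log2r = fit$log2r, t = fit$t, p = fit$p,
               q = bh_adjust(fit$p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Dual-tag differential call for each complex
#'
#' A complex is `accumulated` iff both tags have `log2r > log2r_threshold`
#' and `q < alpha`; `depleted` iff both have `log2r < -log2r_threshold` and
#' `q < alpha`; otherwise `unchanged`. Inequalities are strict.
#'
#' @param stats Long per-tag table as returned by [tag_statistics()].
#' @param log2r_threshold Effect-size cutoff (default 0.25).
#' @param alpha Significance cutoff on the q-value (default 0.05).
#' @return Data frame, one row per complex: `complex_id`, `log2r_up`,
#'   `log2r_down`, `q_up`, `q_down`, `call`.
#' @export
call_complexes <- function(stats, log2r_threshold = 0.25, alpha = 0.05) {
  check_number(log2r_threshold, "log2r_threshold", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  up <- stats[stats$tag == "UP", ]
  dn <- stats[stats$tag == "DOWN", ]
  ids <- sort(unique(stats$complex_id))
  iu <- match(ids, up$complex_id)
  id_ <- match(ids, dn$complex_id)
  if (anyNA(iu) || anyNA(id_))
    warning("complexes missing one tag are treated as unchanged")
  out <- data.frame(
    complex_id = ids,
    log2r_up = up$log2r[iu], log2r_down = dn$log2r[id_],
    q_up = up$q[iu], q_down = dn$q[id_],
    stringsAsFactors = FALSE
  )
  acc <- with(out, log2r_up > log2r_threshold & log2r_down > log2r_threshold &
                q_up < alpha & q_down < alpha)
  dep <- with(out, log2r_up < -log2r_threshold & log2r_down < -log2r_threshold &
                q_up < alpha & q_down < alpha)
  acc[is.na(acc)] <- FALSE
  dep[is.na(dep)] <- FALSE
  out$call <- ifelse(acc, "accumulated", ifelse(dep, "depleted", "unchanged"))
  out
}

#' Tag-effect exclusions from the non-selective control screen
#'
#' Complexes called accumulated or depleted in -MTX media responded to the
#' condition independently of complex formation (the PCA fragment itself
#' perturbs growth); they are excluded from the selective analysis of that
#' condition.
#'
#' @param minus_mtx_calls Call table from the -MTX arrays (same thresholds
#'   as the selective screen).
#' @return Character vector of excluded `complex_id`s.
#' @export
identify_tag_effects <- function(minus_mtx_calls) {
  minus_mtx_calls$complex_id[minus_mtx_calls$call %in%
                               c("accumulated", "depleted")]
}

# Fragment identifiers for each strain: protein_a carries the F[1,2]
# fragment and protein_b the F[3] fragment.
fragment_table <- function(network) {
  data.frame(
    complex_id = rep(network$complex_id, 2L),
    fragment = c(paste0(network$protein_a, "-F12"),
                 paste0(network$protein_b, "-F3")),
    stringsAsFactors = FALSE
  )
}

#' Extend tag-effect exclusions to recurrently artifactual fragments
#'
#' If a specific PCA fragment (a protein fused to either the F\[1,2\] or the
#' F\[3\] half) occurs more than once among a condition's excluded strains,
#' every complex carrying that fragment is excluded "by association".
#'
#' @param excluded Character vector of complex ids excluded for direct
#'   selection-independent growth changes.
#' @param network Edge table (`protein_a`, `protein_b`, `complex_id`).
#' @return Character vector of additional complex ids (not already in
#'   `excluded`) excluded by association.
#' @export
exclude_by_association <- function(excluded, network) {
  if (length(excluded) == 0) return(character(0))
  frags <- fragment_table(network)
  hit <- frags$fragment[frags$complex_id %in% excluded]
  recurrent <- names(which(table(hit) > 1))
  extra <- unique(frags$complex_id[frags$fragment %in% recurrent])
  setdiff(extra, excluded)
}

#' Full dual-screen calling for one condition
#'
#' Orchestrates the per-condition analysis: statistics and calls on the
#' selective (+MTX) arrays, the same machinery with identical thresholds on
#' the non-selective (-MTX) arrays, direct and by-association exclusions,
#' and the final call table in which excluded strains are flagged rather
#' than called.
#'
#' @param x A `"pca_intensity"` object (raw, unless `normalize = FALSE` and
#'   already on the log2 scale).
#' @param network Edge table with `protein_a`, `protein_b`, `complex_id`.
#' @param condition,control Condition labels.
#' @param log2r_threshold,alpha Call thresholds (see [call_complexes()]).
#' @param normalize Apply [quantile_normalize()] first (default `TRUE`).
#' @return Call table as [call_complexes()], with `call` additionally taking
#'   the values `"excluded_tag_effect"` and `"excluded_by_association"`, and
#'   a `counts` attribute recording the stage bookkeeping.
#' @export
bcpca_calls <- function(x, network, condition, control = "control",
                        log2r_threshold = 0.25, alpha = 0.05,
                        normalize = TRUE) {
  if (normalize) x <- quantile_normalize(x)
  plus <- call_complexes(tag_statistics(x, condition, control, "plusMTX"),
                         log2r_threshold, alpha)
  minus <- call_complexes(tag_statistics(x, condition, control, "minusMTX"),
                          log2r_threshold, alpha)
  direct <- identify_tag_effects(minus)
  assoc <- exclude_by_association(direct, network)
  out <- plus
  out$call[out$complex_id %in% direct] <- "excluded_tag_effect"
  out$call[out$complex_id %in% assoc] <- "excluded_by_association"
  attr(out, "counts") <- c(
    complexes = nrow(out),
    excluded_minus_mtx = length(direct),
    excluded_by_association = length(assoc),
    accumulated = sum(out$call == "accumulated"),
    depleted = sum(out$call == "depleted")
  )
  out
}

#' Summarize dynamic-complex frequencies across conditions
#'
#' Given a combined call table over several conditions, counts how many
#' complexes were dynamic (accumulated or depleted) in at least one
#' condition, in one to three conditions, and in four or more, plus the
#' number of conditions with at least `min_changes` dynamic complexes.
#'
#' @param calls Data frame with columns `complex_id`, `condition`, `call`.
#' @param min_changes Threshold for a condition to count as having
#'   widespread changes (default 50).
#' @return Named numeric vector: `dynamic`, `dynamic_1_3`, `dynamic_4_plus`,
#'   `conditions_ge_min`.
#' @export
summarize_call_table <- function(calls, min_changes = 50) {
  dyn <- calls[calls$call %in% c("accumulated", "depleted"), ]
  freq <- table(dyn$complex_id)
  per_cond <- table(dyn$condition)
  c(dynamic = length(freq),
    dynamic_1_3 = sum(freq >= 1 & freq <= 3),
    dynamic_4_plus = sum(freq >= 4),
    conditions_ge_min = sum(per_cond >= min_changes))
}

#' Growth-curve area under the curve
#'
#' The mean of the first ten optical-density readings is subtracted from the
#' whole series (baseline zeroing) and the AUC is the sum of the adjusted
#' readings.
#'
#' @param od Numeric vector of OD600 readings at regular intervals.
#' @param baseline_n Number of initial readings averaged for the baseline.
#' @return The AUC (summed OD units).
#' @export
growth_auc <- function(od, baseline_n = 10) {
  if (length(od) < baseline_n)
    stop_input("need at least %d OD readings", baseline_n)
  sum(od - mean(od[seq_len(baseline_n)]))
}

#' Relative growth of a condition against its control
#'
#' `(AUC_condition - AUC_control) / AUC_control`.
#'
#' @param auc_cond,auc_ctrl Areas under the growth curve.
#' @return Relative growth (dimensionless).
#' @export
relative_growth <- function(auc_cond, auc_ctrl) {
  (auc_cond - auc_ctrl) / auc_ctrl
}

#' qPCR expression ratio by the delta-delta-Ct method
#'
#' `ratio = 2^(dCt_reference - dCt_gene)` where `dCt = Ct_treated -
#' Ct_control` for the gene of interest and the reference gene (ACT1 role).
#'
#' @param ct_gene_treated,ct_gene_control Ct values for the target gene.
#' @param ct_ref_treated,ct_ref_control Ct values for the reference gene.
#' @return Fold change of the target transcript (treated / control),
#'   normalized to the reference gene.
#' @export
qpcr_ratio <- function(ct_gene_treated, ct_gene_control,
                       ct_ref_treated, ct_ref_control) {
  d_gene <- ct_gene_treated - ct_gene_control
  d_ref <- ct_ref_treated - ct_ref_control
  2^(d_ref - d_gene)
}
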