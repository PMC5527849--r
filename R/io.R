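# Tab-delimited interchange formats and pipeline orchestration.
#
# All stage inputs and outputs are UTF-8 TSV with a header row and '.'
# decimal separator, mirroring supplementary-table conventions. Intensity
# tables carry their array metadata in the column header as
# "condition|replicate|selection".

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop_input("%s: missing column(s) %s", path,
               paste(missing, collapse = ", "))
  for (cn in intersect(numeric_cols, names(d))) {
    if (!is.numeric(d[[cn]]))
      stop_input("%s: column '%s' must be numeric", path, cn)
  }
  d
}

#' Read an interaction network edge table
#'
#' Columns: `protein_a`, `protein_b`, `complex_id`, `up_tag`, `down_tag`.
#' ORF ids are uppercased; duplicate complex ids are an error.
#'
#' @param path TSV path.
#' @return Validated edge data frame.
#' @export
read_network_tsv <- function(path) {
  d <- read_tsv_checked(path, c("protein_a", "protein_b", "complex_id",
                                "up_tag", "down_tag"))
  d$protein_a <- toupper(d$protein_a)
  d$protein_b <- toupper(d$protein_b)
  if (anyDuplicated(d$complex_id))
    stop_input("%s: duplicate complex_id values", path)
  d
}

#' Read a protein abundance table (PaxDB convention)
#'
#' Columns: `orf`, `ppm` (ppm > 0).
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_abundance_tsv <- function(path) {
  d <- read_tsv_checked(path, c("orf", "ppm"), numeric_cols = "ppm")
  d$orf <- toupper(d$orf)
  if (any(!is.finite(d$ppm) | d$ppm <= 0))
    stop_input("%s: ppm values must be positive", path)
  d
}

#' Read an expression log2-ratio table
#'
#' Column `orf` plus one or more numeric timepoint columns; empty cells are
#' missing measurements.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_expression_tsv <- function(path) {
  d <- read_tsv_checked(path, "orf")
  d$orf <- toupper(d$orf)
  for (cn in setdiff(names(d), "orf"))
    if (!is.numeric(d[[cn]]) && !all(is.na(d[[cn]])))
      stop_input("%s: timepoint column '%s' must be numeric", path, cn)
  d
}

#' Write / read barcode intensity tables
#'
#' Rows are tags (`complex_id` and `tag` columns), remaining columns are
#' arrays named `condition|replicate|selection`.
#'
#' @param x A [pca_intensity()] object.
#' @param path TSV path.
#' @return `write_intensities_tsv` returns `path` invisibly;
#'   `read_intensities_tsv` returns a `"pca_intensity"` object (raw scale
#'   assumed).
#' @export
write_intensities_tsv <- function(x, path) {
  stopifnot(inherits(x, "pca_intensity"))
  hdr <- sprintf("%s|%s|%s", x$cols$condition, x$cols$replicate,
                 x$cols$selection)
  d <- cbind(x$rows[, c("complex_id", "tag")],
             as.data.frame(x$values, optional = TRUE))
  names(d) <- c("complex_id", "tag", hdr)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensities_tsv
#' @export
read_intensities_tsv <- function(path) {
  d <- read_tsv_checked(path, c("complex_id", "tag"))
  arr <- setdiff(names(d), c("complex_id", "tag"))
  if (length(arr) == 0) stop_input("%s: no array columns", path)
  meta <- strsplit(arr, "|", fixed = TRUE)
  if (any(lengths(meta) != 3))
    stop_input("%s: array headers must be condition|replicate|selection", path)
  cols <- data.frame(condition = vapply(meta, `[`, "", 1),
                     replicate = as.integer(vapply(meta, `[`, "", 2)),
                     selection = vapply(meta, `[`, "", 3),
                     stringsAsFactors = FALSE)
  vals <- as.matrix(d[, arr, drop = FALSE])
  if (!is.numeric(vals)) stop_input("%s: non-numeric intensity cells", path)
  pca_intensity(vals, d[, c("complex_id", "tag")], cols)
}

write_stage_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all tables of a synthetic study to a directory
#'
#' Produces `intensities.tsv`, `network.tsv`, `abundance.tsv`,
#' `expression.tsv`, and `truth.tsv`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_intensities_tsv(study$intensities, file.path(dir, "intensities.tsv"))
  write_stage_tsv(study$network, file.path(dir, "network.tsv"))
  write_stage_tsv(study$abundance, file.path(dir, "abundance.tsv"))
  write_stage_tsv(study$expression, file.path(dir, "expression.tsv"))
  truth <- study$truth$edges
  write_stage_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Run the full analysis pipeline on one study
#'
#' Executes calling, hub/topology analysis, mass-action prediction, and
#' variance partitioning on in-memory inputs, writing every stage output
#' plus a manifest to `out_dir`. Deterministic under a fixed seed.
#'
#' @param intensities A raw [pca_intensity()] object.
#' @param network,abundance,expression Input tables (see the readers).
#' @param out_dir Output directory.
#' @param condition,control Condition labels for the contrast.
#' @param log2r_threshold,alpha,discordance_threshold,hub_min_partners,min_dynamic
#'   Analysis thresholds (paper-procedure defaults).
#' @param node_fractions,n_sims Topology-simulation settings.
#' @param timepoint Expression timepoint for the mass-action stage.
#' @param noise Optional [noise_model()]; when supplied the variance
#'   partition stage runs with `n_noise_replicates` replicates.
#' @param n_noise_replicates Noise-added replicates for the partition stage.
#' @param seed Master seed for the stochastic stages.
#' @return A manifest list (also written to `manifest.tsv`): per-stage row
#'   counts and bookkeeping.
#' @export
run_pipeline <- function(intensities, network, abundance, expression,
                         out_dir, condition = "treatment",
                         control = "control",
                         log2r_threshold = 0.25, alpha = 0.05,
                         discordance_threshold = 1, hub_min_partners = 10,
                         min_dynamic = 50,
                         node_fractions = seq(0, 1, by = 0.1), n_sims = 1000,
                         timepoint = "t4", noise = NULL,
                         n_noise_replicates = 100, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  calls <- bcpca_calls(intensities, network, condition, control,
                       log2r_threshold, alpha)
  write_stage_tsv(calls, file.path(out_dir, "calls.tsv"))

  cons <- data.frame(complex_id = calls$complex_id, condition = condition,
                     log2r = conservative_log2r(calls$log2r_up,
                                                calls$log2r_down),
                     stringsAsFactors = FALSE)
  hubs <- find_hubs(network, hub_min_partners)
  hub_bias <- hub_directional_bias(network, cons, hubs, alpha)
  if (!is.null(hub_bias))
    write_stage_tsv(hub_bias, file.path(out_dir, "hubs.tsv"))

  labels <- ifelse(calls$call %in% c("accumulated", "depleted"),
                   calls$call, "unchanged")
  labels <- labels[match(network$complex_id, calls$complex_id)]
  topo <- simulate_topology(network, labels, node_fractions, n_sims,
                            metric = "largest_component",
                            min_dynamic = min_dynamic,
                            seed = substream_seed(seed, 11))
  write_stage_tsv(topo$results, file.path(out_dir, "netdyn.tsv"))

  pred <- predict_complex_ratios(network, abundance, expression, timepoint)
  pred$included <- discordance_filter(calls$log2r_up, calls$log2r_down,
                                      discordance_threshold)[
    match(pred$complex_id, calls$complex_id)]
  write_stage_tsv(pred, file.path(out_dir, "predictions.tsv"))

  part <- NULL
  if (!is.null(noise)) {
    observed <- data.frame(complex_id = cons$complex_id, log2r = cons$log2r)
    part <- partition_distribution(
      pred[pred$included, ], observed, expression, network, abundance, noise,
      timepoint = timepoint, n_replicates = n_noise_replicates,
      seed = substream_seed(seed, 12))
    write_stage_tsv(part$samples, file.path(out_dir, "partition.tsv"))
  }

  manifest <- list(
    seed = seed,
    counts = attr(calls, "counts"),
    n_hubs = length(hubs),
    best_node_fraction = topo$best_fraction,
    n_predictions = nrow(pred),
    n_excluded_discordant = sum(!pred$included, na.rm = TRUE),
    rho_mod_sq_median = if (!is.null(part)) part$median else NA_real_
  )
  mdf <- data.frame(key = c("seed", names(manifest$counts), "n_hubs",
                            "best_node_fraction", "n_predictions",
                            "n_excluded_discordant", "rho_mod_sq_median"),
                    value = c(seed, unname(manifest$counts),
                              manifest$n_hubs, manifest$best_node_fraction,
                              manifest$n_predictions,
                              manifest$n_excluded_discordant,
                              manifest$rho_mod_sq_median))
  write_stage_tsv(mdf, file.path(out_dir, "manifest.tsv"))
  manifest
}
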