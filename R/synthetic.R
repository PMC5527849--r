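# Synthetic BC-PCA study generator with exported ground truth.
#
# Emulates the study design end to end: an interaction network with planted
# hubs, log-normal resting protein abundances, a condition that perturbs a
# known set of proteins (protein-centric effects, propagated to complexes
# through the mass-action model) and a known set of individual edges
# (interaction-specific shifts applied directly to complex levels), barcode
# intensity arrays for both selections with the paper's replicate design
# (duplicate treatment, six-fold control), and coupled expression data.
# One master seed drives deterministic per-stage substreams.

#' Specification of a synthetic BC-PCA study
#'
#' Defaults describe a desk-scale version of the study design: duplicate
#' treatment arrays against six control replicates in both selections, a
#' network large enough to carry planted hubs with ten or more partners,
#' log-normal abundances on the PaxDB ppm scale, and log2-scale Gaussian
#' noise for tags, replicates, and expression.
#'
#' @param n_proteins,n_interactions Network size.
#' @param hub_count Number of planted hubs.
#' @param hub_min_degree Minimum partner count per planted hub (default 10).
#' @param homodimer_prob Probability that a filler edge is a self-edge.
#' @param abundance_log_mean,abundance_log_sd Mean and sd of log10 ppm.
#' @param n_node_effects Number of proteins with a true concentration
#'   change.
#' @param protein_fold_change_range Interval (log2) from which protein
#'   changes are drawn uniformly.
#' @param edge_effect_count Number of interaction-specific perturbations.
#' @param edge_effect_range Interval (log2) for interaction-specific shifts.
#' @param n_treatment_reps,n_control_reps Replication per selection.
#' @param tag_noise_sd,replicate_noise_sd,expression_noise_sd Noise
#'   magnitudes on the log2 scale.
#' @param expression_missing_fraction Fraction of genes reported missing in
#'   the expression table (exercises the R = 1 fallback).
#' @param kd_divisor Kd divisor used when computing true complex levels.
#' @param seed Master seed; identical specs produce identical studies.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_proteins = 400, n_interactions = 800,
                           hub_count = 8, hub_min_degree = 10,
                           homodimer_prob = 0.02,
                           abundance_log_mean = 1.3, abundance_log_sd = 1,
                           n_node_effects = 20,
                           protein_fold_change_range = c(-2, 2),
                           edge_effect_count = 10,
                           edge_effect_range = c(-2, 2),
                           n_treatment_reps = 2, n_control_reps = 6,
                           tag_noise_sd = 0.1, replicate_noise_sd = 0.1,
                           expression_noise_sd = 0.2,
                           expression_missing_fraction = 0,
                           kd_divisor = 20, seed = 1) {
  check_number(n_proteins, "n_proteins", lower = 2, integer = TRUE)
  check_number(n_interactions, "n_interactions", lower = 1, integer = TRUE)
  check_number(hub_count, "hub_count", lower = 0, integer = TRUE)
  check_number(hub_min_degree, "hub_min_degree", lower = 1, integer = TRUE)
  check_number(homodimer_prob, "homodimer_prob", lower = 0, upper = 1)
  check_number(n_node_effects, "n_node_effects", lower = 0, integer = TRUE)
  check_number(edge_effect_count, "edge_effect_count", lower = 0, integer = TRUE)
  check_number(n_treatment_reps, "n_treatment_reps", lower = 2, integer = TRUE)
  check_number(n_control_reps, "n_control_reps", lower = 2, integer = TRUE)
  check_number(tag_noise_sd, "tag_noise_sd", lower = 0)
  check_number(replicate_noise_sd, "replicate_noise_sd", lower = 0)
  check_number(expression_noise_sd, "expression_noise_sd", lower = 0)
  check_number(expression_missing_fraction, "expression_missing_fraction",
               lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)
  max_edges <- n_proteins * (n_proteins - 1) / 2 + n_proteins
  if (n_interactions > max_edges)
    stop_input("n_interactions exceeds the number of distinct protein pairs")
  if (hub_count > 0 && ceiling(hub_count * hub_min_degree / 2) > n_interactions)
    stop_input("infeasible spec: %d hubs of degree >= %d need more than %d edges",
               hub_count, hub_min_degree, n_interactions)
  if (hub_count >= n_proteins)
    stop_input("hub_count must be smaller than n_proteins")
  structure(as.list(environment())[names(formals(synthetic_spec))],
            class = "synthetic_spec")
}

protein_ids <- function(n) sprintf("YP%04d", seq_len(n))

#' Generate the synthetic interaction network
#'
#' Hubs are planted explicitly: each of the first `hub_count` proteins is
#' wired to at least `hub_min_degree` randomly chosen distinct partners;
#' remaining edges are uniform random pairs (self-edges with probability
#' `homodimer_prob`). Every edge carries a unique complex id and UP/DOWN
#' tag ids.
#'
#' @param spec A [synthetic_spec()].
#' @return Edge data frame: `protein_a`, `protein_b`, `complex_id`,
#'   `up_tag`, `down_tag`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, 1), {
    prots <- protein_ids(spec$n_proteins)
    hubs <- prots[seq_len(spec$hub_count)]
    seen <- new.env(hash = TRUE)
    partners <- new.env(hash = TRUE)
    a <- character(0); b <- character(0)
    add_edge <- function(p, q) {
      key <- paste(sort(c(p, q)), collapse = "|")
      if (!is.null(seen[[key]])) return(FALSE)
      seen[[key]] <- TRUE
      partners[[p]] <- union(partners[[p]] %||% character(0), q)
      partners[[q]] <- union(partners[[q]] %||% character(0), p)
      a[[length(a) + 1L]] <<- p
      b[[length(b) + 1L]] <<- q
      TRUE
    }
    # Wire hubs to each other first (sharing edges between hubs keeps the
    # edge budget close to hub_count * hub_min_degree / 2), then top each
    # hub up with random non-hub partners.
    for (h in hubs) {
      have <- partners[[h]] %||% character(0)
      pool <- sample(setdiff(hubs, c(h, have)))
      for (p in pool) {
        if (length(partners[[h]] %||% character(0)) >= spec$hub_min_degree)
          break
        add_edge(h, p)
      }
      deficit <- spec$hub_min_degree - length(partners[[h]] %||% character(0))
      if (deficit > 0) {
        pool <- sample(setdiff(prots, c(h, hubs, partners[[h]] %||% character(0))))
        for (p in pool[seq_len(min(deficit, length(pool)))]) add_edge(h, p)
      }
      if (length(partners[[h]] %||% character(0)) < spec$hub_min_degree)
        stop_input("not enough proteins to satisfy hub degrees")
    }
    if (length(a) > spec$n_interactions)
      stop_input("edge budget too small for the requested hub wiring (%d edges needed)",
                 length(a))
    while (length(a) < spec$n_interactions) {
      if (stats::runif(1) < spec$homodimer_prob) {
        p <- sample(prots, 1)
        add_edge(p, p)
      } else {
        pq <- sample(prots, 2)
        add_edge(pq[1], pq[2])
      }
    }
    n <- length(a)
    data.frame(protein_a = a, protein_b = b,
               complex_id = sprintf("CPX%04d", seq_len(n)),
               up_tag = sprintf("U%04d", seq_len(n)),
               down_tag = sprintf("D%04d", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

#' Generate resting protein abundances
#'
#' Log-normal on the log10-ppm scale, mirroring the spread of genomewide
#' proteome abundance compilations.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame: `orf`, `ppm`.
#' @export
generate_abundances <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, 2), {
    prots <- protein_ids(spec$n_proteins)
    data.frame(orf = prots,
               ppm = 10^stats::rnorm(length(prots), spec$abundance_log_mean,
                                     spec$abundance_log_sd),
               stringsAsFactors = FALSE)
  })
}

#' Generate the condition's ground truth
#'
#' `n_node_effects` randomly chosen proteins receive a log2 concentration
#' change drawn uniformly from `protein_fold_change_range`. Every edge
#' incident to a perturbed protein is `node_driven`: its true complex level
#' in the condition is recomputed through the mass-action closed form from
#' the scaled partner concentrations (Kd fixed at its reference value).
#' `edge_effect_count` of the remaining edges are `edge_driven`: their
#' complex level is shifted directly by a log2 amount drawn from
#' `edge_effect_range`, capped at the concentration of the limiting
#' partner. All other edges are `static`.
#'
#' @param network Output of [generate_network()].
#' @param abundances Output of [generate_abundances()].
#' @param spec A [synthetic_spec()].
#' @return List of class `"ground_truth"`: `protein_log2fc` (named vector,
#'   all proteins), `edges` (data frame: `complex_id`, `mechanism`,
#'   `c_ref`, `c_cond`, `true_log2_ratio`), `node_effect_fraction`
#'   (realized fraction of dynamic edges that are node-driven).
#' @export
generate_condition_state <- function(network, abundances, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!all(c(network$protein_a, network$protein_b) %in% abundances$orf))
    stop_input("every network protein needs an abundance entry")
  if (spec$n_node_effects > spec$n_proteins)
    stop_input("n_node_effects exceeds the number of proteins")
  with_seed(substream_seed(spec$seed, 3), {
    prots <- abundances$orf
    fc <- stats::setNames(numeric(length(prots)), prots)
    perturbed <- sample(prots, spec$n_node_effects)
    fc[perturbed] <- stats::runif(spec$n_node_effects,
                                  spec$protein_fold_change_range[1],
                                  spec$protein_fold_change_range[2])

    c1 <- abundances$ppm[match(network$protein_a, prots)]
    c2 <- abundances$ppm[match(network$protein_b, prots)]
    kd <- assign_kd(c1, c2, spec$kd_divisor)
    c_ref <- complex_concentration(c1, c2, kd)

    node_driven <- network$protein_a %in% perturbed |
      network$protein_b %in% perturbed
    candidates <- which(!node_driven)
    if (spec$edge_effect_count > length(candidates))
      stop_input("edge_effect_count exceeds the number of non-node-driven edges")
    edge_idx <- candidates[sample.int(length(candidates),
                                      spec$edge_effect_count)]

    r1 <- 2^fc[network$protein_a]
    r2 <- 2^fc[network$protein_b]
    c_cond <- c_ref
    c_cond[node_driven] <- complex_concentration(
      (r1 * c1)[node_driven], (r2 * c2)[node_driven], kd[node_driven])
    if (length(edge_idx)) {
      shift <- stats::runif(length(edge_idx), spec$edge_effect_range[1],
                            spec$edge_effect_range[2])
      cap <- pmin(c1[edge_idx], c2[edge_idx])
      c_cond[edge_idx] <- pmin(c_ref[edge_idx] * 2^shift, cap)
    }
    mechanism <- rep("static", nrow(network))
    mechanism[node_driven] <- "node_driven"
    mechanism[edge_idx] <- "edge_driven"

    n_dyn <- sum(mechanism != "static")
    structure(list(
      protein_log2fc = fc,
      edges = data.frame(complex_id = network$complex_id,
                         mechanism = mechanism,
                         c_ref = c_ref, c_cond = c_cond,
                         true_log2_ratio = log2(c_cond / c_ref),
                         stringsAsFactors = FALSE),
      node_effect_fraction =
        if (n_dyn > 0) sum(mechanism == "node_driven") / n_dyn else NA_real_
    ), class = "ground_truth")
  })
}

#' Simulate the barcode intensity arrays
#'
#' One UP- and one DOWN-tag row per complex. Each tag receives a fixed
#' baseline (complex level plus a tag-efficiency offset); treatment columns
#' under MTX selection additionally carry the true complex log2 ratio.
#' Replicate noise is shared by the two tags of a strain within an array;
#' tag noise is independent per tag and array. Values are returned on the
#' linear fluorescence scale.
#'
#' @param network Output of [generate_network()].
#' @param truth Output of [generate_condition_state()].
#' @param spec A [synthetic_spec()].
#' @param tag_fitness Optional named log2 shifts (by `complex_id`) applied
#'   to treatment columns of BOTH selections, emulating strains whose PCA
#'   fragment perturbs growth independently of selection.
#' @return A [pca_intensity()] object (raw scale) with conditions
#'   `"treatment"` and `"control"`.
#' @export
simulate_assay <- function(network, truth, spec, tag_fitness = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  with_seed(substream_seed(spec$seed, 4), {
    n <- nrow(network)
    cols <- do.call(rbind, lapply(c("plusMTX", "minusMTX"), function(sel)
      rbind(
        data.frame(condition = "control",
                   replicate = seq_len(spec$n_control_reps),
                   selection = sel, stringsAsFactors = FALSE),
        data.frame(condition = "treatment",
                   replicate = seq_len(spec$n_treatment_reps),
                   selection = sel, stringsAsFactors = FALSE))))
    rows <- data.frame(
      complex_id = rep(network$complex_id, 2L),
      tag = rep(c("UP", "DOWN"), each = n),
      stringsAsFactors = FALSE)

    base_complex <- log2(truth$edges$c_ref) + 8
    tag_offset <- stats::rnorm(2L * n, 0, 0.5)
    baseline <- rep(base_complex, 2L) + tag_offset

    shift <- truth$edges$true_log2_ratio
    tagfit <- numeric(n)
    if (!is.null(tag_fitness)) {
      i <- match(names(tag_fitness), network$complex_id)
      if (anyNA(i)) stop_input("tag_fitness names must be complex ids")
      tagfit[i] <- tag_fitness
    }

    m <- matrix(0, nrow = 2L * n, ncol = nrow(cols))
    for (j in seq_len(nrow(cols))) {
      is_treat <- cols$condition[j] == "treatment"
      eff <- numeric(n)
      if (is_treat && cols$selection[j] == "plusMTX") eff <- eff + shift
      if (is_treat) eff <- eff + tagfit
      rep_noise <- stats::rnorm(n, 0, spec$replicate_noise_sd)
      tag_noise <- stats::rnorm(2L * n, 0, spec$tag_noise_sd)
      m[, j] <- baseline + rep(eff, 2L) + rep(rep_noise, 2L) + tag_noise
    }
    pca_intensity(2^m, rows, cols, log2 = FALSE, normalized = FALSE)
  })
}

#' Generate coupled expression data
#'
#' Per-gene log2 expression ratios equal the true protein log2 change plus
#' Gaussian noise, at two timepoints (`t1`, `t4`) with independent noise so
#' the replicate correlation needed by the variance-partition stage can be
#' estimated. A configurable fraction of genes is set missing (`NA`) to
#' exercise the downstream R = 1 fallback.
#'
#' @param truth Output of [generate_condition_state()].
#' @param spec A [synthetic_spec()].
#' @return Data frame: `orf`, `t1`, `t4` (log2 ratios, `NA` when missing).
#' @export
generate_expression <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  with_seed(substream_seed(spec$seed, 5), {
    fc <- truth$protein_log2fc
    n <- length(fc)
    out <- data.frame(
      orf = names(fc),
      t1 = fc + stats::rnorm(n, 0, spec$expression_noise_sd),
      t4 = fc + stats::rnorm(n, 0, spec$expression_noise_sd),
      stringsAsFactors = FALSE)
    if (spec$expression_missing_fraction > 0) {
      miss <- stats::runif(n) < spec$expression_missing_fraction
      out$t1[miss] <- NA_real_
      out$t4[miss] <- NA_real_
    }
    out
  })
}

#' Generate a complete synthetic study
#'
#' Runs all four generators off one master seed.
#'
#' @param spec A [synthetic_spec()].
#' @param tag_fitness Passed to [simulate_assay()].
#' @return List: `spec`, `network`, `abundance`, `truth`, `intensities`,
#'   `expression`.
#' @export
simulate_study <- function(spec, tag_fitness = NULL) {
  network <- generate_network(spec)
  abundance <- generate_abundances(spec)
  truth <- generate_condition_state(network, abundance, spec)
  list(spec = spec,
       network = network,
       abundance = abundance,
       truth = truth,
       intensities = simulate_assay(network, truth, spec, tag_fitness),
       expression = generate_expression(truth, spec))
}
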