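# Null models for dynamic-subnetwork topology.
#
# Observed per-condition labelings (accumulated / depleted / unchanged) are
# compared against labelings simulated under two mechanisms:
#
#  * node-based ("protein-centric"): a random protein is proposed to have
#    ALL of its interactions change in the current direction; the proposal
#    is accepted iff it would not push that direction's label count past
#    its quota. Directions alternate (starting with accumulated) until both
#    quotas are met exactly. Relabeling may flip edges previously assigned
#    the other direction — the most recent assignment wins — in which case
#    sampling of the deficient direction simply resumes.
#
#  * edge-based ("interaction-specific"): labels are assigned uniformly at
#    random to still-static edges.
#
# Mixtures assign round(fraction * quota) labels per direction with the
# node-based sampler and the remainder edge-based.

# Build node -> incident-edge-index list once per network.
incidence_index <- function(network) {
  nodes <- unique(c(network$protein_a, network$protein_b))
  idx_a <- split(seq_len(nrow(network)), factor(network$protein_a, nodes))
  idx_b <- split(seq_len(nrow(network)), factor(network$protein_b, nodes))
  lapply(stats::setNames(nodes, nodes), function(n)
    unique(c(idx_a[[n]], idx_b[[n]])))
}

#' Node-based (protein-centric) labeling sampler
#'
#' @param network Edge table, or a precomputed incidence list from
#'   `incidence_index()` supplied via `incidence`.
#' @param quota_acc,quota_dep Exact numbers of accumulated and depleted
#'   edge labels to produce.
#' @param incidence Optional precomputed incidence list (for reuse across
#'   many simulations).
#' @param labels Optional starting label vector (integer: 0 unchanged,
#'   1 accumulated, 2 depleted); used internally by the mixture sampler.
#' @param max_attempts Because relabeling can flip previously assigned
#'   edges, the alternating process can cycle without converging on dense
#'   graphs with large quotas; each attempt is bounded by a proposal budget
#'   and the sampler restarts from scratch, erroring (never silently
#'   truncating) once `max_attempts` attempts are exhausted.
#' @return Character vector of edge labels (`"accumulated"`, `"depleted"`,
#'   `"unchanged"`), parallel to the network rows.
#' @export
sample_node_based <- function(network, quota_acc, quota_dep,
                              incidence = NULL, labels = NULL,
                              max_attempts = 25) {
  inc <- incidence %||% incidence_index(network)
  n_edges <- nrow(network)
  check_number(quota_acc, "quota_acc", lower = 0, integer = TRUE)
  check_number(quota_dep, "quota_dep", lower = 0, integer = TRUE)
  if (quota_acc + quota_dep > n_edges)
    stop_input("quotas exceed the number of edges")
  quotas <- c(quota_acc, quota_dep)
  n_nodes <- length(inc)
  budget <- max(2000L, 60L * n_nodes)

  for (attempt in seq_len(max_attempts)) {
    lab <- labels %||% integer(n_edges)
    counts <- c(sum(lab == 1L), sum(lab == 2L))
    dir <- 1L
    proposals <- 0L
    while (counts[1L] < quotas[1L] || counts[2L] < quotas[2L]) {
      if (counts[dir] >= quotas[dir]) { dir <- 3L - dir; next }
      proposals <- proposals + 1L
      if (proposals > budget) break
      cand <- inc[[sample.int(n_nodes, 1L)]]
      gain <- sum(lab[cand] != dir)
      if (counts[dir] + gain <= quotas[dir]) {
        flipped <- sum(lab[cand] == (3L - dir))
        counts[3L - dir] <- counts[3L - dir] - flipped
        lab[cand] <- dir
        counts[dir] <- counts[dir] + gain
        dir <- 3L - dir
      }
    }
    if (counts[1L] == quotas[1L] && counts[2L] == quotas[2L])
      return(c("unchanged", "accumulated", "depleted")[lab + 1L])
  }
  stop(sprintf(
    "node-based sampler failed to meet quotas (%d, %d) after %d attempts",
    quota_acc, quota_dep, max_attempts))
}

#' Mixture labeling sampler
#'
#' `round(node_fraction * quota)` labels per direction are drawn with the
#' node-based sampler; the remainder are assigned uniformly at random to
#' still-static edges, so final counts equal the quotas exactly.
#'
#' @inheritParams sample_node_based
#' @param node_fraction Fraction of each direction's quota produced by the
#'   node-based mechanism, in \[0, 1\].
#' @return Character label vector, parallel to the network rows.
#' @export
sample_mixture <- function(network, node_fraction, quota_acc, quota_dep,
                           incidence = NULL) {
  check_number(node_fraction, "node_fraction", lower = 0, upper = 1)
  inc <- incidence %||% incidence_index(network)
  n_edges <- nrow(network)
  node_acc <- round(node_fraction * quota_acc)
  node_dep <- round(node_fraction * quota_dep)

  lab_chr <- if (node_acc + node_dep > 0)
    sample_node_based(network, node_acc, node_dep, incidence = inc)
  else rep("unchanged", n_edges)
  lab <- match(lab_chr, c("unchanged", "accumulated", "depleted")) - 1L

  need_acc <- quota_acc - sum(lab == 1L)
  need_dep <- quota_dep - sum(lab == 2L)
  static <- which(lab == 0L)
  if (need_acc + need_dep > length(static))
    stop("not enough static edges for the edge-based phase")
  pick <- static[sample.int(length(static), need_acc + need_dep)]
  lab[pick[seq_len(need_acc)]] <- 1L
  if (need_dep > 0) lab[pick[need_acc + seq_len(need_dep)]] <- 2L
  c("unchanged", "accumulated", "depleted")[lab + 1L]
}

# Percentile of `obs` within the empirical distribution `sims`, linearly
# interpolated between order statistics (plotting positions (i-0.5)/n).
empirical_percentile <- function(obs, sims) {
  n <- length(sims)
  s <- sort(sims)
  if (obs <= s[1L]) return(if (obs < s[1L]) 0 else 100 * 0.5 / n)
  if (obs >= s[n]) return(if (obs > s[n]) 100 else 100 * (n - 0.5) / n)
  pp <- (seq_len(n) - 0.5) / n
  100 * stats::approx(s, pp, xout = obs, ties = "ordered")$y
}

#' Percentile-consistency analysis of dynamic-subnetwork topology
#'
#' For each candidate `node_fraction`, simulates `n_sims` labelings with the
#' observed accumulated/depleted quotas, measures the chosen topology metric
#' separately for the accumulated and depleted subnetworks, and places the
#' observed metric on the empirical percentile scale. A fraction is
#' *consistent* when the observed metric lies within the simulated 5th-95th
#' percentile band for both directions. The best-fitting fraction minimizes
#' the larger of the two percentile departures from the median
#' (`|percentile - 50|`); ties go to the smaller fraction.
#'
#' @param network Edge table.
#' @param labels Observed edge labels (character, parallel to network rows).
#' @param node_fractions Grid of protein-centric fractions to evaluate.
#' @param n_sims Simulated labelings per fraction (default 1000).
#' @param metric `"largest_component"` or `"density"`.
#' @param min_dynamic Warn when the observed labeling has fewer dynamic
#'   edges than this (the analysis loses power; default 50).
#' @param seed Optional seed making the simulation reproducible.
#' @return List with `results` (data frame: `node_fraction`, `direction`,
#'   `p5`, `p95`, `observed`, `percentile`, `departure`, `consistent`),
#'   `by_fraction` (max departure and joint consistency per fraction), and
#'   `best_fraction`.
#' @export
simulate_topology <- function(network, labels,
                              node_fractions = seq(0, 1, by = 0.1),
                              n_sims = 1000,
                              metric = c("largest_component", "density"),
                              min_dynamic = 50, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(labels) == nrow(network))
  quota_acc <- sum(labels == "accumulated")
  quota_dep <- sum(labels == "depleted")
  if (quota_acc + quota_dep < min_dynamic)
    warning(sprintf("only %d dynamic edges; percentile bands will be unstable",
                    quota_acc + quota_dep))
  inc <- incidence_index(network)
  dirs <- c("accumulated", "depleted")
  observed <- vapply(dirs, function(d)
    dynamic_subgraph(network, labels, d)[[metric]], numeric(1))

  run <- function() {
    rows <- list()
    for (f in node_fractions) {
      sims <- matrix(NA_real_, nrow = n_sims, ncol = 2,
                     dimnames = list(NULL, dirs))
      for (i in seq_len(n_sims)) {
        lab <- sample_mixture(network, f, quota_acc, quota_dep, incidence = inc)
        for (d in dirs)
          sims[i, d] <- dynamic_subgraph(network, lab, d)[[metric]]
      }
      for (d in dirs) {
        qs <- stats::quantile(sims[, d], c(0.05, 0.95), names = FALSE)
        perc <- empirical_percentile(observed[d], sims[, d])
        rows[[length(rows) + 1L]] <- data.frame(
          node_fraction = f, direction = d,
          p5 = qs[1], p95 = qs[2], observed = observed[d],
          percentile = perc, departure = abs(perc - 50),
          consistent = observed[d] >= qs[1] & observed[d] <= qs[2],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  results <- if (is.null(seed)) run() else with_seed(seed, run())
  rownames(results) <- NULL

  by_fraction <- do.call(rbind, lapply(split(results, results$node_fraction),
    function(d) data.frame(node_fraction = d$node_fraction[1],
                           max_departure = max(d$departure),
                           consistent = all(d$consistent))))
  by_fraction <- by_fraction[order(by_fraction$node_fraction), ]
  rownames(by_fraction) <- NULL
  best <- by_fraction$node_fraction[which.min(by_fraction$max_departure)]
  list(results = results, by_fraction = by_fraction, best_fraction = best)
}
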