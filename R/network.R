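# Hub statistics and dynamic-subnetwork topology.
#
# The interaction network is an undirected protein graph in which each edge
# is one PCA strain (one binary complex); self-edges represent homodimers.
# "Hubs" are proteins with >= 10 distinct interaction partners; a self-edge
# contributes one partner (the protein itself).

# Convert an edge table to an igraph graph (nodes = proteins).
network_graph <- function(network) {
  stopifnot(all(c("protein_a", "protein_b", "complex_id") %in% names(network)))
  igraph::graph_from_data_frame(
    network[, c("protein_a", "protein_b")], directed = FALSE)
}

# Distinct-partner count per protein (self-edge counts the protein once).
partner_counts <- function(network) {
  pairs <- unique(rbind(
    data.frame(p = network$protein_a, q = network$protein_b,
               stringsAsFactors = FALSE),
    data.frame(p = network$protein_b, q = network$protein_a,
               stringsAsFactors = FALSE)
  ))
  tab <- table(pairs$p)
  stats::setNames(as.integer(tab), names(tab))
}

#' Identify hub proteins
#'
#' Hubs are proteins with at least `min_partners` distinct interaction
#' partners. A homodimer self-edge contributes one partner.
#'
#' @param network Edge table (`protein_a`, `protein_b`, `complex_id`).
#' @param min_partners Partner-count threshold (default 10).
#' @return Character vector of hub protein ids.
#' @export
find_hubs <- function(network, min_partners = 10) {
  if (nrow(network) == 0) stop_input("network is empty")
  counts <- partner_counts(network)
  names(counts)[counts >= min_partners]
}

#' Conservative per-strain log2 ratio
#'
#' Of a strain's two tag ratios, returns the one closest to zero (smallest
#' absolute value); ties return the UP-tag value. This is a deliberately
#' conservative single-number summary of the complex-level change.
#'
#' @param log2r_up,log2r_down Tag log2 ratios. Vectorized.
#' @return Numeric vector of conservative log2 ratios.
#' @export
conservative_log2r <- function(log2r_up, log2r_down) {
  ifelse(abs(log2r_down) < abs(log2r_up), log2r_down, log2r_up)
}

#' Mann-Whitney U test with the package's exact/approximate switch
#'
#' Exact enumeration when both groups have at most `exact_max` observations
#' and no ties across groups; otherwise the normal approximation with
#' continuity correction (ties handled by the rank-based approximation).
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for which the exact distribution is
#'   enumerated (default 8).
#' @return List with elements `u` (the U statistic for `x`) and `p`
#'   (two-sided p-value).
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(u = unname(ht$statistic), p = ht$p.value)
}

#' Directional bias of hub-incident complex changes
#'
#' For every (hub, condition) pair, compares the conservative log2 ratios of
#' the complexes containing the hub against those of all other complexes
#' with a two-sided Mann-Whitney U test, then BH-adjusts across all pairs
#' jointly. The bias direction is the sign of the difference in group
#' medians.
#'
#' @param network Edge table.
#' @param values Data frame with columns `complex_id`, `condition`, and
#'   `log2r` (conservative per-strain ratios).
#' @param hubs Hub protein ids; defaults to [find_hubs()] on `network`.
#' @param alpha Significance cutoff used for the `biased` flag.
#' @param min_complexes Hubs with fewer incident complexes measured in a
#'   condition are skipped with a warning.
#' @return Data frame: `hub`, `condition`, `n_complexes`, `direction`
#'   (`"accumulation"` or `"depletion"`), `p`, `q`, `biased`.
#' @export
hub_directional_bias <- function(network, values, hubs = NULL, alpha = 0.05,
                                 min_complexes = 2) {
  hubs <- hubs %||% find_hubs(network)
  incident <- lapply(stats::setNames(hubs, hubs), function(h) {
    network$complex_id[network$protein_a == h | network$protein_b == h]
  })
  conditions <- unique(values$condition)
  rows <- list()
  for (cond in conditions) {
    v <- values[values$condition == cond, ]
    for (h in hubs) {
      inc <- v$log2r[v$complex_id %in% incident[[h]]]
      rest <- v$log2r[!v$complex_id %in% incident[[h]]]
      if (length(inc) < min_complexes) {
        warning(sprintf("hub %s has < %d measured complexes in %s; skipped",
                        h, min_complexes, cond))
        next
      }
      mw <- mann_whitney(inc, rest)
      rows[[length(rows) + 1L]] <- data.frame(
        hub = h, condition = cond, n_complexes = length(inc),
        direction = if (stats::median(inc) >= stats::median(rest))
          "accumulation" else "depletion",
        p = mw$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- bh_adjust(out$p)
  out$biased <- out$q < alpha
  rownames(out) <- NULL
  out
}

#' Topology of a same-direction dynamic subnetwork
#'
#' Induces the subgraph of edges labeled with `direction`, with vertex set
#' the proteins incident to at least one such edge, and returns the node
#' count of its largest connected component together with the subgraph
#' density `2|E| / (|V| (|V| - 1))`. With no edges, both are zero; a
#' single-vertex subgraph (lone homodimer) has density 0 by convention.
#'
#' @param network Edge table.
#' @param labels Character vector of edge labels, parallel to the rows of
#'   `network` (values `"accumulated"`, `"depleted"`, `"unchanged"`).
#' @param direction The label whose subnetwork is measured.
#' @return List: `largest_component` (node count), `density`, `n_edges`,
#'   `n_nodes`.
#' @export
dynamic_subgraph <- function(network, labels, direction) {
  stopifnot(length(labels) == nrow(network))
  sel <- labels == direction
  n_e <- sum(sel)
  if (n_e == 0)
    return(list(largest_component = 0L, density = 0, n_edges = 0L, n_nodes = 0L))
  sub <- network[sel, , drop = FALSE]
  nodes <- unique(c(sub$protein_a, sub$protein_b))
  g <- igraph::graph_from_data_frame(sub[, c("protein_a", "protein_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  n_v <- length(nodes)
  dens <- if (n_v >= 2) 2 * n_e / (n_v * (n_v - 1)) else 0
  list(largest_component = as.integer(max(comp$csize)), density = dens,
       n_edges = as.integer(n_e), n_nodes = as.integer(n_v))
}

#' First- and second-neighbor response around a focal protein
#'
#' Tests whether the complexes containing a focal protein (first neighbors),
#' and the complexes containing a partner of the focal protein but not the
#' protein itself (second neighbors), shifted relative to the remaining
#' complexes in the pool, by two-sided Mann-Whitney U tests against the
#' complexes in neither group.
#'
#' @param network Edge table.
#' @param focal Focal protein id.
#' @param values Data frame with columns `complex_id` and `log2r`.
#' @return List: `p_first`, `p_second`, `n_first`, `n_second`.
#' @export
neighbor_depletion_test <- function(network, focal, values) {
  if (!focal %in% c(network$protein_a, network$protein_b))
    stop_input("focal protein '%s' is not in the network", focal)
  first_ids <- network$complex_id[network$protein_a == focal |
                                    network$protein_b == focal]
  partners <- setdiff(unique(c(
    network$protein_b[network$protein_a == focal],
    network$protein_a[network$protein_b == focal])), focal)
  second_ids <- setdiff(
    network$complex_id[network$protein_a %in% partners |
                         network$protein_b %in% partners],
    first_ids)
  base <- values[!values$complex_id %in% c(first_ids, second_ids), ]
  first <- values$log2r[values$complex_id %in% first_ids]
  second <- values$log2r[values$complex_id %in% second_ids]
  p_first <- if (length(first)) mann_whitney(first, base$log2r)$p else NA_real_
  p_second <- if (length(second)) mann_whitney(second, base$log2r)$p else NA_real_
  list(p_first = p_first, p_second = p_second,
       n_first = length(first), n_second = length(second))
}
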