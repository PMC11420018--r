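#' Node strength and bridge strength centrality
#'
#' Strength is the sum of the absolute weights of a node's connections;
#' bridge strength restricts that sum to edges reaching nodes outside the
#' node's own group (here: emotion regulation, depression, anxiety), the
#' cross-cluster portion that flags bridge symptoms.
#'
#' @param net a `weighted_network`.
#' @param groups optional named vector overriding the groups stored on the
#'   network's nodes.
#' @return data.frame with `node_id`, `group`, `strength`,
#'   `bridge_strength`, and z-scored variants (`strength_z`,
#'   `bridge_strength_z`) for plotting.
#' @export
centrality_table <- function(net, groups = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  aw <- abs(net$weights)
  strength <- rowSums(aw)
  if (is.null(groups)) {
    groups <- setNames(net$nodes$group, net$nodes$node_id)
  }
  ids <- net$nodes$node_id
  if (any(!ids %in% names(groups)) || anyNA(groups[ids]))
    stop("node(s) missing a group assignment: ",
         paste(setdiff(ids, names(groups)), collapse = ", "))
  grp <- groups[ids]
  bridge <- vapply(seq_along(ids), function(i) {
    sum(aw[i, grp != grp[i]])
  }, numeric(1))
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  data.frame(node_id = ids, group = unname(grp),
             strength = unname(strength), bridge_strength = bridge,
             strength_z = zs(unname(strength)), bridge_strength_z = zs(bridge),
             stringsAsFactors = FALSE)
}

#' @rdname centrality_table
#' @export
node_strength <- function(net) {
  setNames(rowSums(abs(net$weights)), net$nodes$node_id)
}

#' @rdname centrality_table
#' @export
bridge_strength <- function(net, groups = NULL) {
  ct <- centrality_table(net, groups = groups)
  setNames(ct$bridge_strength, ct$node_id)
}

#' Global network properties
#'
#' Edge counts, density, and negative-edge count are read off the signed
#' weighted matrix; average path length, global transitivity, and mean local
#' clustering are computed on the binarized graph (an edge is present iff
#' its weight is nonzero), the convention for reporting these descriptives
#' on regularized psychometric networks. Weighted variants (inverse-weight
#' path lengths, weighted clustering) are available via `weighted = TRUE`.
#'
#' @param net a `weighted_network`.
#' @param weighted compute path length / transitivity / clustering on the
#'   weighted graph instead of the binarized one.
#' @return List: `density`, `n_edges`, `n_negative_edges`,
#'   `average_path_length` (over connected pairs), `transitivity`,
#'   `clustering_coefficient` (mean local clustering over nodes with at
#'   least two neighbours), `connected` flag.
#' @export
global_properties <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  p <- nrow(w)
  ut <- w[upper.tri(w)]
  n_edges <- sum(ut != 0)
  n_neg <- sum(ut < 0)
  density <- if (p > 1) n_edges / (p * (p - 1) / 2) else 0

  adj <- abs(w)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  connected <- p <= 1 || igraph::is_connected(g)
  if (n_edges == 0) {
    apl <- NA_real_; trans <- NA_real_; clust <- NA_real_
  } else if (weighted) {
    apl <- igraph::mean_distance(g, weights = 1 / abs(igraph::E(g)$weight))
    trans <- igraph::transitivity(g, type = "global")
    clust <- mean(igraph::transitivity(g, type = "barrat",
                                       weights = igraph::E(g)$weight),
                  na.rm = TRUE)
    if (is.nan(clust)) clust <- NA_real_
  } else {
    apl <- igraph::mean_distance(g, weights = NA)
    trans <- igraph::transitivity(g, type = "global")
    loc <- igraph::transitivity(g, type = "local", weights = NA)
    clust <- if (all(is.na(loc))) NA_real_ else mean(loc, na.rm = TRUE)
  }
  list(density = density, n_edges = n_edges, n_negative_edges = n_neg,
       average_path_length = apl, transitivity = trans,
       clustering_coefficient = clust, connected = connected)
}
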