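#' Read and write item-response matrices as CSV
#'
#' The on-disk form is one header row of item identifiers and one integer
#' row per participant. Reading validates the schema against the item
#' metadata (every item present, every cell inside its legal code range, no
#' missing cells) and errors with the offending row/column.
#'
#' @param path CSV file path.
#' @param items item metadata, as [default_item_meta()].
#' @return [read_item_csv()]: an `item_response_matrix`.
#' @export
read_item_csv <- function(path, items = default_item_meta()) {
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(items$item_id, colnames(df))
  if (length(missing) > 0)
    stop("CSV is missing item column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(df), items$item_id)
  if (length(extra) > 0)
    stop("CSV has unknown column(s): ", paste(extra, collapse = ", "))
  values <- as.matrix(df[, items$item_id, drop = FALSE])
  if (!is.numeric(values) || any(values != round(values), na.rm = TRUE))
    stop("all cells must be integer codes")
  storage.mode(values) <- "integer"
  x <- new_item_response_matrix(values, items)
  validate_item_response_matrix(x)
  x
}

#' @rdname read_item_csv
#' @param data an `item_response_matrix`.
#' @export
write_item_csv <- function(data, path) {
  stopifnot(inherits(data, "item_response_matrix"))
  write.csv(as.data.frame(data$values), path, row.names = FALSE)
  invisible(path)
}

#' Long-format edge list of a network
#'
#' @param net a `weighted_network`.
#' @return data.frame `node_a`, `node_b`, `weight`, `estimator_tag`, one
#'   row per nonzero edge (upper triangle).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(node_a = rownames(w)[idx[, 1]], node_b = colnames(w)[idx[, 2]],
             weight = w[idx],
             estimator_tag = rep(net$estimator_tag, nrow(idx)),
             stringsAsFactors = FALSE)
}

#' Write a network as GraphML with node attributes
#'
#' @param net a `weighted_network`.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$kind <- net$nodes$kind
  igraph::V(g)$group <- net$nodes$group
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# fixed-precision CSV writer: 6 decimals for doubles so repeated runs are
# byte-identical
write_csv_fixed <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6f", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
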