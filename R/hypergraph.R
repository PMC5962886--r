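#' Binary incidence matrix of a hyper-graph
#'
#' @param edges list of integer member vectors (node indices in
#'   `1:n_nodes`).
#' @param n_nodes number of nodes `|V|`.
#' @return `|V| x |E|` 0/1 matrix `H` with `H[v, e] = 1` iff node `v`
#'   belongs to hyper-edge `e`.
#' @export
incidence_matrix <- function(edges, n_nodes) {
  n_nodes <- as.integer(n_nodes)
  H <- matrix(0L, n_nodes, length(edges))
  for (e in seq_along(edges)) {
    members <- unique(as.integer(edges[[e]]))
    if (length(members) && (min(members) < 1L || max(members) > n_nodes))
      stop_hn("hn_schema_error", "edge %d has member outside 1:%d", e, n_nodes)
    H[members, e] <- 1L
  }
  H
}

#' Hyper-graph container
#'
#' Stores the node set, ordered hyper-edge list, incidence matrix and the
#' derived node/edge degrees. Edges are sets: member order never carries
#' meaning and members are stored sorted and unique.
#'
#' @param edges list of integer member vectors.
#' @param n_nodes number of nodes.
#' @param meta optional provenance list (construction method, grid, ...).
#' @return Object of class `hypernetwork` with fields `n_nodes`, `edges`,
#'   `incidence`, `node_degrees`, `edge_degrees`, `meta`.
#' @export
hypernetwork <- function(edges, n_nodes, meta = list()) {
  edges <- lapply(edges, function(e) sort(unique(as.integer(e))))
  H <- incidence_matrix(edges, n_nodes)
  structure(list(
    n_nodes = as.integer(n_nodes),
    edges = edges,
    incidence = H,
    node_degrees = as.integer(rowSums(H)),
    edge_degrees = as.integer(colSums(H)),
    meta = meta
  ), class = "hypernetwork")
}

#' @export
print.hypernetwork <- function(x, ...) {
  cat(sprintf("<hypernetwork> %d nodes, %d hyper-edges (edge degree %s)\n",
              x$n_nodes, length(x$edges),
              if (length(x$edges)) sprintf("%d-%d", min(x$edge_degrees),
                                           max(x$edge_degrees)) else "-"))
  invisible(x)
}

#' Node degree: number of hyper-edges containing a node
#'
#' @param net a [hypernetwork()].
#' @param v node index, or `NULL` for all nodes.
#' @return Integer (vector of) degree(s), the row sum(s) of the incidence
#'   matrix.
#' @export
node_degree <- function(net, v = NULL) {
  if (is.null(v)) return(net$node_degrees)
  net$node_degrees[v]
}

#' Edge degree: number of nodes in a hyper-edge
#'
#' @param net a [hypernetwork()].
#' @param e edge index, or `NULL` for all edges.
#' @return Integer (vector of) size(s), the column sum(s) of the incidence
#'   matrix.
#' @export
edge_degree <- function(net, e = NULL) {
  if (is.null(e)) return(net$edge_degrees)
  net$edge_degrees[e]
}

#' Hyper-graph adjacency matrix
#'
#' `A = H H' - D_v` where `D_v` is the diagonal matrix of node degrees:
#' `A[i, j]` counts the hyper-edges containing both nodes, and the diagonal
#' is zero.
#'
#' @param net a [hypernetwork()].
#' @return Symmetric integer matrix with zero diagonal.
#' @export
adjacency <- function(net) {
  A <- tcrossprod(net$incidence)
  diag(A) <- 0
  A
}

#' Write a hyper-network as an edge-list TSV
#'
#' Columns: `edge_id`, `centroid`, `penalty_fraction`, `members`
#' (comma-separated 1-based node indices). Centroid/penalty columns come
#' from construction metadata when present.
#'
#' @param net a [hypernetwork()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hypernetwork <- function(net, path) {
  n <- length(net$edges)
  centroid <- if (!is.null(net$meta$centroids)) net$meta$centroids else rep(NA_integer_, n)
  frac <- if (!is.null(net$meta$fractions)) net$meta$fractions else rep(NA_real_, n)
  df <- data.frame(
    edge_id = seq_len(n), centroid = centroid, penalty_fraction = frac,
    members = vapply(net$edges, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
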