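#' Single-layer clustering coefficient
#'
#' Fraction of realized edges among a node's neighbours:
#' `c_i = 2 T_i / (k_i (k_i - 1))` where `T_i` counts edges between
#' neighbours of i and `k_i` is the degree. Nodes with fewer than two
#' neighbours have `c_i = 0`.
#'
#' @param adj binary symmetric adjacency matrix with zero diagonal.
#' @param node optional node index; if `NULL`, all nodes are returned.
#' @return Numeric vector (or scalar) of clustering coefficients in
#'   \[0, 1\].
#' @export
#' @examples
#' tri <- matrix(1, 3, 3); diag(tri) <- 0
#' clustering_coefficient(tri)  # 1 1 1
clustering_coefficient <- function(adj, node = NULL) {
  check_adjacency(adj)
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj)  # 2 * T_i
  cc <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  if (is.null(node)) cc else cc[node]
}

#' Single-layer local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbours:
#' the mean inverse shortest-path length over ordered neighbour pairs,
#' with unreachable pairs contributing zero. Nodes with fewer than two
#' neighbours have efficiency 0. This is the convention used by the
#' common brain-network toolboxes.
#'
#' @inheritParams clustering_coefficient
#' @return Numeric vector (or scalar) of local efficiencies in \[0, 1\].
#' @export
#' @examples
#' k4 <- matrix(1, 4, 4); diag(k4) <- 0
#' local_efficiency(k4)  # all 1: every neighbour subgraph is K3
local_efficiency <- function(adj, node = NULL) {
  check_adjacency(adj)
  nodes <- if (is.null(node)) seq_len(nrow(adj)) else node
  eff <- vapply(nodes, function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    d <- igraph::distances(g)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
  if (is.null(node)) eff else unname(eff)
}

check_adjacency <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency must have zero diagonal")
  if (!all(adj %in% c(0, 1))) stop("adjacency must be binary")
  invisible(adj)
}
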