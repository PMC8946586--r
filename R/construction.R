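#' Default proportional-sparsity grid
#'
#' The sparsity thresholds at which every network is binarized:
#' 0.10 to 0.40 in steps of 0.05. At each sparsity the same number of
#' edges is retained for every subject and band, making topologies
#' comparable across networks.
#'
#' @return Numeric vector of sparsities, strictly increasing.
#' @export
default_sparsity_grid <- function() seq(0.10, 0.40, by = 0.05)

# Round half away from zero. Different rounding conventions change edge
# quotas by one (e.g. 0.10 * 4005 = 400.5 -> 401); base::round() rounds
# half to even and would give 400.
round_half_up <- function(x) floor(x + 0.5)

#' Binarize a connectivity matrix at a proportional sparsity
#'
#' Retains exactly `round(sparsity * N(N-1)/2)` undirected edges (half
#' rounded away from zero): the strongest off-diagonal correlations in
#' descending order. By default edges are ranked by raw signed r, so
#' negative correlations enter only if needed to fill the quota; set
#' `mode = "absolute"` to rank by |r|. Ties at the cutoff are broken
#' toward the smaller (i, j) pair index so the result is deterministic.
#'
#' @param conn N x N symmetric numeric matrix (zero diagonal).
#' @param sparsity fraction of possible edges to retain, in (0, 1].
#' @param mode `"signed"` (default) ranks by raw r, `"absolute"` by |r|.
#' @return N x N binary symmetric matrix with zero diagonal.
#' @export
#' @examples
#' r <- matrix(0, 4, 4)
#' r[upper.tri(r)] <- c(0.9, 0.5, 0.7, 0.1, 0.3, -0.2)
#' r <- r + t(r)
#' sum(proportional_threshold(r, 0.5)) / 2  # 3 edges
proportional_threshold <- function(conn, sparsity, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(conn), nrow(conn) == ncol(conn))
  if (!(sparsity > 0 && sparsity <= 1)) stop("sparsity must lie in (0, 1]")
  n <- nrow(conn)
  n_pairs <- n * (n - 1) / 2
  e <- round_half_up(sparsity * n_pairs)
  if (e < 1) stop("edge quota rounds to zero: grid too sparse for N = ", n)
  e <- min(e, n_pairs)
  idx <- which(upper.tri(conn), arr.ind = TRUE)
  vals <- conn[idx]
  if (mode == "absolute") vals <- abs(vals)
  keep <- order(-vals, idx[, 1], idx[, 2])[seq_len(e)]
  adj <- matrix(0, n, n, dimnames = dimnames(conn))
  adj[idx[keep, , drop = FALSE]] <- 1
  adj + t(adj)
}

#' Construct a layer stack
#'
#' A layer stack is the multiplex network: M binary, symmetric,
#' zero-diagonal N x N adjacency matrices over the same node set, one
#' per frequency band, all thresholded at the same proportional
#' sparsity. For the canonical analysis M = 4 (slow5--slow2; the full
#' band is excluded from the multilayer model).
#'
#' @param conns named list of per-band connectivity matrices sharing N;
#'   layer order follows the list order.
#' @param sparsity proportional threshold applied to every layer.
#' @param mode edge-ranking mode, see [proportional_threshold()].
#' @return An object of class `layer_stack`: a list with elements
#'   `layers` (list of binary matrices), `layer_names`, `n_nodes`,
#'   `n_layers`, `sparsity`.
#' @export
build_layer_stack <- function(conns, sparsity, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is.list(conns), length(conns) >= 1)
  ns <- vapply(conns, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop("connectivity matrices disagree on N: ", paste(ns, collapse = ", "))
  }
  layers <- lapply(conns, proportional_threshold, sparsity = sparsity, mode = mode)
  layer_stack(layers, layer_names = names(conns), sparsity = sparsity)
}

#' Assemble a layer stack from adjacency matrices
#'
#' Lower-level constructor used by [build_layer_stack()] and by tests:
#' wraps already-binarized adjacency matrices into a `layer_stack`.
#'
#' @param layers list of binary symmetric N x N matrices, zero diagonal.
#' @param layer_names optional character vector of layer names.
#' @param sparsity optional sparsity annotation.
#' @return A `layer_stack` object.
#' @export
layer_stack <- function(layers, layer_names = NULL, sparsity = NA_real_) {
  stopifnot(is.list(layers), length(layers) >= 1)
  n <- nrow(layers[[1]])
  for (a in layers) {
    stopifnot(is.matrix(a), nrow(a) == n, ncol(a) == n)
    if (any(a != t(a))) stop("layer adjacency must be symmetric")
    if (any(diag(a) != 0)) stop("layer adjacency must have zero diagonal")
    if (!all(a %in% c(0, 1))) stop("layer adjacency must be binary")
  }
  if (is.null(layer_names)) layer_names <- paste0("layer", seq_along(layers))
  structure(
    list(layers = layers, layer_names = layer_names, n_nodes = n,
         n_layers = length(layers), sparsity = sparsity),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer_stack: %d nodes, %d layers (%s), sparsity %s\n",
              x$n_nodes, x$n_layers, paste(x$layer_names, collapse = ", "),
              format(x$sparsity)))
  edges <- vapply(x$layers, function(a) sum(a) / 2, numeric(1))
  cat("edges per layer:", paste(edges, collapse = ", "), "\n")
  invisible(x)
}

#' Supra-adjacency matrix
#'
#' The (N M) x (N M) block representation of the multiplex network:
#' layer adjacencies on the diagonal blocks and N-dimensional identity
#' matrices on every off-diagonal block, coupling each node to its
#' counterparts in the other layers. The node metrics (MCC, EMD) read
#' only the diagonal blocks; the supra-adjacency is provided for
#' completeness and export.
#'
#' @param stack a `layer_stack`.
#' @return Binary symmetric (N M) x (N M) matrix; rows/columns are
#'   ordered layer-major (all nodes of layer 1, then layer 2, ...).
#' @export
build_supra_adjacency <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  n <- stack$n_nodes
  m <- stack$n_layers
  supra <- matrix(0, n * m, n * m)
  eye <- diag(n)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      rows <- (a - 1) * n + seq_len(n)
      cols <- (b - 1) * n + seq_len(n)
      supra[rows, cols] <- if (a == b) stack$layers[[a]] else eye
    }
  }
  supra
}
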