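#' AUC aggregation over the sparsity grid
#'
#' Summarizes a metric's curve over the sparsity grid into one number,
#' removing the dependence on any single threshold. The default is the
#' normalized AUC: the trapezoidal integral divided by the grid width,
#' i.e. a trapezoid-weighted mean that preserves the metric's natural
#' scale (a constant curve returns the constant, and an entropy curve
#' stays below its ln M ceiling). Set `normalized = FALSE` for the raw
#' trapezoidal integral.
#'
#' @param values metric values, one per grid sparsity.
#' @param sparsities strictly increasing sparsity grid, length >= 2.
#' @param normalized divide by the grid width (default `TRUE`).
#' @return Scalar AUC.
#' @export
#' @examples
#' auc_over_grid(rep(3, 7), default_sparsity_grid())  # 3
auc_over_grid <- function(values, sparsities = default_sparsity_grid(),
                          normalized = TRUE) {
  if (length(values) != length(sparsities)) {
    stop("values and sparsities differ in length (",
         length(values), " vs ", length(sparsities), ")")
  }
  if (length(sparsities) < 2) stop("need at least 2 grid points")
  if (any(diff(sparsities) <= 0)) stop("sparsities must be strictly increasing")
  area <- pracma::trapz(sparsities, values)
  if (normalized) area / (max(sparsities) - min(sparsities)) else area
}

#' Row-wise AUC over a values matrix
#'
#' @param values_matrix nodes x thresholds matrix.
#' @inheritParams auc_over_grid
#' @return Numeric vector, one AUC per row.
#' @export
auc_rows <- function(values_matrix, sparsities = default_sparsity_grid(),
                     normalized = TRUE) {
  stopifnot(is.matrix(values_matrix), ncol(values_matrix) == length(sparsities))
  apply(values_matrix, 1, auc_over_grid, sparsities = sparsities,
        normalized = normalized)
}

rsn_labels <- c("default_mode", "attention", "sensorimotor", "subcortical", "visual")

#' Read a node-to-RSN mapping file
#'
#' The mapping file is tab-delimited with a header and columns
#' `node_index` (1-based, matching the region order of the time-series
#' matrices), `region_label`, and `rsn_label` (one of `default_mode`,
#' `attention`, `sensorimotor`, `subcortical`, `visual`). Every node
#' must be mapped exactly once.
#'
#' @param path path to the mapping file.
#' @return data.frame with the three columns, ordered by `node_index`.
#' @export
read_rsn_mapping <- function(path) {
  if (!file.exists(path)) stop("RSN mapping file not found: ", path)
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_index", "region_label", "rsn_label")
  if (!all(need %in% names(map))) {
    stop("RSN mapping ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(map$rsn_label), rsn_labels)
  if (length(bad)) {
    stop("unknown RSN label(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  map <- map[order(map$node_index), , drop = FALSE]
  if (!identical(as.integer(map$node_index), seq_len(nrow(map)))) {
    stop("node_index in ", path, " must be exactly 1..N with no gaps or duplicates")
  }
  rownames(map) <- NULL
  map
}

#' Default AAL-90 to RSN mapping
#'
#' A reconstruction of the assignment of the 90 AAL cortical and
#' subcortical regions to five resting-state networks (default-mode,
#' attention, sensorimotor, subcortical, visual), assembled from the
#' functional-template literature. It is shipped as a convenience
#' default and clearly marked as a synthetic reconstruction
#' (`aal90_rsn_synthetic.tsv`): analyses of real data should supply a
#' mapping file matching their parcellation.
#'
#' @return data.frame as in [read_rsn_mapping()].
#' @export
default_rsn_mapping <- function() {
  path <- system.file("extdata", "aal90_rsn_synthetic.tsv", package = "mplexfc",
                      mustWork = TRUE)
  read_rsn_mapping(path)
}

#' Aggregate node values to RSN means
#'
#' Arithmetic mean of per-node (AUC-scale) values within each
#' resting-state network.
#'
#' @param values numeric vector of per-node values, length N.
#' @param mapping data.frame from [read_rsn_mapping()], or a character
#'   vector of RSN labels of length N.
#' @return Named numeric vector of RSN means (names sorted).
#' @export
rsn_aggregate <- function(values, mapping) {
  labels <- if (is.data.frame(mapping)) mapping$rsn_label else as.character(mapping)
  if (length(labels) != length(values)) {
    stop("mapping covers ", length(labels), " nodes but values has ",
         length(values))
  }
  if (anyNA(labels)) {
    stop("unmapped node(s): ", paste(which(is.na(labels)), collapse = ", "))
  }
  means <- tapply(values, labels, mean)
  means[sort(names(means))]
}
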