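#' Write and read subject time series
#'
#' Time-series files are tab-separated: a header row of timepoint
#' indices (`t1`, `t2`, ...), then one row per region whose first
#' column is the region label.
#'
#' @param x regions x timepoints numeric matrix with region row names.
#' @param path output file path.
#' @return `write_time_series` returns `path` invisibly;
#'   `read_time_series` returns the matrix.
#' @export
write_time_series <- function(x, path) {
  stopifnot(is.matrix(x))
  if (is.null(rownames(x))) rownames(x) <- sprintf("R%03d", seq_len(nrow(x)))
  df <- data.frame(region = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("region", paste0("t", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_series
#' @export
read_time_series <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "region") {
    stop("malformed time-series file ", path, ": first column must be 'region'")
  }
  x <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(x) || anyNA(x)) {
    stop("malformed time-series file ", path, ": non-numeric or missing values")
  }
  rownames(x) <- df$region
  colnames(x) <- NULL
  x
}

#' Write and read square labeled matrices
#'
#' Connectivity and adjacency matrices are written as tab-separated
#' square tables with matching row and column labels.
#'
#' @param m square numeric matrix.
#' @param path file path.
#' @return `write_square_matrix` returns `path` invisibly;
#'   `read_square_matrix` returns the matrix.
#' @export
write_square_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- sprintf("R%03d", seq_len(nrow(m)))
  }
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_square_matrix
#' @export
read_square_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  m
}

#' Export a layer stack as an edge list
#'
#' Tab-separated columns `node_i`, `node_j`, `layer` (one row per
#' undirected edge, i < j).
#'
#' @param stack a `layer_stack`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(stack, path) {
  stopifnot(inherits(stack, "layer_stack"))
  rows <- list()
  for (a in seq_len(stack$n_layers)) {
    idx <- which(upper.tri(stack$layers[[a]]) & stack$layers[[a]] == 1,
                 arr.ind = TRUE)
    if (nrow(idx)) {
      rows[[length(rows) + 1]] <- data.frame(
        node_i = idx[, 1], node_j = idx[, 2],
        layer = stack$layer_names[a], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_i = integer(), node_j = integer(), layer = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read a synthetic cohort directory
#'
#' A cohort directory holds `manifest.tsv` (columns `subject_id`,
#' `group`, `sans`, `saps`) and one time-series file per subject
#' (`<subject_id>_timeseries.tsv`).
#'
#' @param cohort a `synth_cohort` (or any list with `manifest` and
#'   `series`).
#' @param dir output directory (created if missing).
#' @param tr_seconds repetition time to attach when reading.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort`
#'   returns a list with `manifest` and `series`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$series)) {
    write_time_series(cohort$series[[id]],
                      file.path(dir, paste0(id, "_timeseries.tsv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(manifest))) {
    stop("malformed manifest ", manifest_path,
         ": needs subject_id and group columns")
  }
  series <- lapply(manifest$subject_id, function(id) {
    read_time_series(file.path(dir, paste0(id, "_timeseries.tsv")))
  })
  names(series) <- manifest$subject_id
  ns <- vapply(series, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop("subjects disagree on region count: ",
         paste(unique(ns), collapse = ", "))
  }
  list(manifest = manifest, series = series, tr_seconds = tr_seconds)
}
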