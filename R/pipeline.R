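#' Analysis pipeline configuration
#'
#' Collects every tunable decision of the analysis in one place: the
#' band table (the full band participates only in single-layer
#' analyses; the multilayer stack always uses the slow bands), the
#' sparsity grid, the MCC convention, the edge-ranking mode, the AUC
#' normalization, and the significance level.
#'
#' @param bands band table including the full band
#'   (default [canonical_bands()]).
#' @param grid sparsity grid (default [default_sparsity_grid()]).
#' @param mcc_convention `"literal"` or `"strict_three_layer"`.
#' @param threshold_mode `"signed"` or `"absolute"` edge ranking.
#' @param auc_normalized logical; normalized AUC (default `TRUE`).
#' @param alpha significance level (default 0.05).
#' @param filter_order Butterworth design order (default 2).
#' @param include_single_layer compute per-band Cp and Eloc (default
#'   `TRUE`; the multiplex metrics alone are much cheaper).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(bands = canonical_bands(),
                            grid = default_sparsity_grid(),
                            mcc_convention = c("literal", "strict_three_layer"),
                            threshold_mode = c("signed", "absolute"),
                            auc_normalized = TRUE,
                            alpha = 0.05,
                            filter_order = 2L,
                            include_single_layer = TRUE) {
  mcc_convention <- match.arg(mcc_convention)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(alpha > 0, alpha < 1, length(grid) >= 2, all(diff(grid) > 0))
  structure(list(bands = bands, grid = grid,
                 mcc_convention = mcc_convention,
                 threshold_mode = threshold_mode,
                 auc_normalized = auc_normalized,
                 alpha = alpha, filter_order = as.integer(filter_order),
                 include_single_layer = include_single_layer),
            class = "pipeline_config")
}

#' Per-subject network metrics
#'
#' Runs the per-subject stages: band-pass decomposition, Pearson
#' connectivity per band, proportional thresholding over the sparsity
#' grid, multiplex metrics (EMD, MCC, overlapping degree) on the
#' four-slow-band stack, optional single-layer metrics (Cp, Eloc) per
#' band, and normalized AUC aggregation over the grid.
#'
#' @param ts regions x timepoints matrix.
#' @param tr_seconds repetition time in seconds.
#' @param config a [pipeline_config()].
#' @return List with vectors `emd_auc`, `mcc_auc`, `overlap_auc`
#'   (length N) and, when `include_single_layer`, matrices `cp_auc`,
#'   `eloc_auc` (N x bands).
#' @export
subject_metrics <- function(ts, tr_seconds, config = pipeline_config()) {
  stopifnot(is.matrix(ts))
  filtered <- bandpass_all(ts, config$bands, tr_seconds, config$filter_order)
  conns <- lapply(filtered, pearson_connectivity)
  slow <- intersect(c("slow5", "slow4", "slow3", "slow2"), names(conns))
  if (length(slow) < 2) stop("multilayer analysis needs at least 2 slow bands")
  n <- nrow(ts)
  grid <- config$grid
  emd <- mcc <- ovl <- matrix(NA_real_, n, length(grid))
  if (config$include_single_layer) {
    cp <- eloc <- array(NA_real_, c(n, length(grid), nrow(config$bands)),
                        dimnames = list(NULL, NULL, config$bands$name))
  }
  for (g in seq_along(grid)) {
    stack <- build_layer_stack(conns[slow], grid[g], mode = config$threshold_mode)
    emd[, g] <- node_emd(stack)
    mcc[, g] <- node_mcc(stack, convention = config$mcc_convention)
    ovl[, g] <- overlap_degree(stack)
    if (config$include_single_layer) {
      for (b in seq_len(nrow(config$bands))) {
        adj <- proportional_threshold(conns[[config$bands$name[b]]], grid[g],
                                      mode = config$threshold_mode)
        cp[, g, b] <- clustering_coefficient(adj)
        eloc[, g, b] <- local_efficiency(adj)
      }
    }
  }
  out <- list(
    emd_auc = auc_rows(emd, grid, config$auc_normalized),
    mcc_auc = auc_rows(mcc, grid, config$auc_normalized),
    overlap_auc = auc_rows(ovl, grid, config$auc_normalized)
  )
  if (config$include_single_layer) {
    out$cp_auc <- apply(cp, 3, function(m) auc_rows(m, grid, config$auc_normalized))
    out$eloc_auc <- apply(eloc, 3, function(m) auc_rows(m, grid, config$auc_normalized))
  }
  out
}

#' Run the end-to-end group analysis
#'
#' For every subject: band-pass filtering, connectivity, thresholding
#' over the grid, node metrics, AUC aggregation; then group statistics
#' (node / RSN / whole-brain pooled t-tests with BH-FDR within each
#' family), symptom-score correlations within the patient group, and
#' between-layer clustering-sequence correlations per group.
#' Deterministic given the cohort.
#'
#' @param cohort a `synth_cohort`, or the list returned by
#'   [read_cohort()].
#' @param config a [pipeline_config()].
#' @param mapping optional RSN mapping (data.frame or label vector);
#'   enables RSN-level comparisons.
#' @param verbose log per-stage progress (default `FALSE`).
#' @return List of class `mplexfc_results` with elements `metrics`
#'   (named list of subjects x nodes AUC matrices), `analysis`
#'   (see [run_group_analysis()]), `layer_cc` (per-group Spearman
#'   matrices of mean clustering sequences across layers incl. MCC),
#'   and `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), mapping = NULL,
                         verbose = FALSE) {
  manifest <- cohort$manifest
  series <- cohort$series
  tr <- if (!is.null(cohort$tr_seconds)) cohort$tr_seconds else
    cohort$config$tr_seconds
  n_sub <- nrow(manifest)
  stopifnot(n_sub >= 4)
  n <- nrow(series[[1]])
  for (id in manifest$subject_id) {
    if (nrow(series[[id]]) != n) {
      stop("subject ", id, " has ", nrow(series[[id]]),
           " regions; expected ", n)
    }
  }
  per_subject <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    per_subject[[i]] <- subject_metrics(series[[i]], tr, config)
    if (verbose && i %% 10 == 0) {
      message("processed ", i, "/", n_sub, " subjects")
    }
  }
  names(per_subject) <- manifest$subject_id

  gather <- function(field) {
    m <- t(vapply(per_subject, `[[`, numeric(n), field))
    rownames(m) <- manifest$subject_id
    colnames(m) <- rownames(series[[1]])
    m
  }
  metrics <- list(emd = gather("emd_auc"), mcc = gather("mcc_auc"))
  if (config$include_single_layer) {
    for (b in config$bands$name) {
      mcp <- t(vapply(per_subject, function(s) s$cp_auc[, b], numeric(n)))
      mel <- t(vapply(per_subject, function(s) s$eloc_auc[, b], numeric(n)))
      rownames(mcp) <- rownames(mel) <- manifest$subject_id
      metrics[[paste0("cp_", b)]] <- mcp
      metrics[[paste0("eloc_", b)]] <- mel
    }
  }
  analysis <- run_group_analysis(metrics, manifest, mapping = mapping,
                                 alpha = config$alpha)

  layer_cc <- NULL
  if (config$include_single_layer) {
    layer_cc <- lapply(c(TD = "TD", SCHZ = "SCHZ"), function(grp) {
      ids <- manifest$subject_id[manifest$group == grp]
      seqs <- lapply(setdiff(config$bands$name, "full"), function(b) {
        colMeans(metrics[[paste0("cp_", b)]][ids, , drop = FALSE])
      })
      names(seqs) <- setdiff(config$bands$name, "full")
      seqs$multilayer <- colMeans(metrics$mcc[ids, , drop = FALSE])
      layer_cc_correlation(seqs)
    })
  }
  structure(list(metrics = metrics, analysis = analysis,
                 layer_cc = layer_cc, config = config),
            class = "mplexfc_results")
}

#' Write pipeline result tables
#'
#' Writes the group-comparison table, the correlation table, and (if
#' present) the per-group layer-correlation matrices as tab-separated
#' text under `dir`.
#'
#' @param results an `mplexfc_results` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results$analysis$comparisons,
                     file.path(dir, "group_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results$analysis$correlations,
                     file.path(dir, "score_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$layer_cc)) {
    for (grp in names(results$layer_cc)) {
      write_square_matrix(results$layer_cc[[grp]],
                          file.path(dir, paste0("layer_cc_", grp, ".tsv")))
    }
  }
  invisible(dir)
}
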