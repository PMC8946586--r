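#' Pooled-variance two-sample t-test
#'
#' Independent-samples t-test with pooled variance (the group
#' comparisons assume equal variances), two-tailed, with
#' `df = n1 + n2 - 2`. Degenerate input with zero pooled variance
#' returns `t = 0, p = 1` when the group means agree and is an error
#' otherwise.
#'
#' @param x,y numeric vectors of the two groups (each length >= 2).
#' @return List with elements `t`, `df`, `p`, `mean_x`, `mean_y`,
#'   `sd_x`, `sd_y`.
#' @export
two_sample_ttest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  pooled_var <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  out <- list(mean_x = mean(x), mean_y = mean(y),
              sd_x = stats::sd(x), sd_y = stats::sd(y),
              df = length(x) + length(y) - 2)
  if (pooled_var == 0) {
    if (mean(x) != mean(y)) stop("zero pooled variance with unequal means")
    out$t <- 0
    out$p <- 1
    return(out)
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), preserving input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Spearman's rho (ranked Pearson, average ranks for ties) with a
#' two-tailed p-value from the t-approximation.
#'
#' @param x,y numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return List with elements `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1, two-tailed.
#' Used for categorical demographics (e.g. a sex-by-group table).
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return List with elements `chi2`, `df`, `p`.
#' @export
#' @examples
#' chi_square_2x2(rbind(c(42, 27), c(38, 12)))$p  # 0.083
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Between-layer clustering-sequence correlations
#'
#' Pairwise Spearman correlation matrix of per-node clustering
#' sequences across layers (optionally including the multilayer MCC
#' sequence): how similarly the layers rank the nodes by local
#' clustering. Self-correlations are 1 by construction. A constant
#' sequence has no rank ordering; its entries are recorded as `NA` with
#' a warning, never silently set to 0.
#'
#' @param sequences named list of numeric per-node vectors (equal
#'   length N), or an N x L matrix with one column per layer.
#' @return L x L symmetric matrix of Spearman rho with unit diagonal.
#' @export
layer_cc_correlation <- function(sequences) {
  if (is.list(sequences)) {
    lens <- lengths(sequences)
    if (length(unique(lens)) != 1) stop("sequences differ in length")
    mat <- do.call(cbind, sequences)
  } else {
    mat <- as.matrix(sequences)
  }
  if (ncol(mat) < 2) stop("need at least 2 layers")
  l <- ncol(mat)
  out <- matrix(NA_real_, l, l, dimnames = list(colnames(mat), colnames(mat)))
  constant <- apply(mat, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning("constant clustering sequence(s): ",
            paste(colnames(mat)[constant], collapse = ", "),
            "; correlations recorded as NA")
  }
  for (a in seq_len(l)) {
    for (b in seq_len(l)) {
      if (a == b) {
        out[a, b] <- 1
      } else if (!constant[a] && !constant[b]) {
        out[a, b] <- stats::cor(mat[, a], mat[, b], method = "spearman")
      }
    }
  }
  out
}

#' Group comparison and symptom-correlation analysis
#'
#' Runs the full statistical stage on AUC-scale node metrics: pooled
#' two-sample t-tests (patients vs controls) at the node, RSN, and
#' whole-brain levels, with Benjamini-Hochberg FDR correction applied
#' within each family (one family per metric per scale: all nodes of a
#' metric, all RSNs of a metric), and Spearman correlations between
#' node metrics and symptom scores within the patient group (controls
#' carry no symptom scores). Patients with a missing score are excluded
#' from that score's correlations with a warning.
#'
#' @param metrics named list of subjects x nodes matrices (AUC scale),
#'   with rownames equal to `manifest$subject_id`.
#' @param manifest data.frame with columns `subject_id`, `group`
#'   (`"TD"`/`"SCHZ"`), and optionally `sans`, `saps` (scores, `NA` for
#'   controls).
#' @param mapping optional RSN mapping (see [read_rsn_mapping()]); if
#'   supplied, RSN-level comparisons are included.
#' @param alpha significance level recorded in the result (default
#'   0.05).
#' @return List with data.frames `comparisons` (columns `unit`, `name`,
#'   `metric`, `mean_schz`, `sd_schz`, `mean_td`, `sd_td`, `t`, `df`,
#'   `p_raw`, `p_fdr`) and `correlations` (columns `metric`, `node`,
#'   `name`, `score`, `rho`, `p`), plus `alpha`.
#' @export
run_group_analysis <- function(metrics, manifest, mapping = NULL, alpha = 0.05) {
  stopifnot(is.list(metrics), length(metrics) >= 1,
            all(c("subject_id", "group") %in% names(manifest)))
  if (!all(manifest$group %in% c("TD", "SCHZ"))) {
    stop("group labels must be TD or SCHZ")
  }
  schz_ids <- manifest$subject_id[manifest$group == "SCHZ"]
  td_ids <- manifest$subject_id[manifest$group == "TD"]

  comparisons <- list()
  for (metric in names(metrics)) {
    m <- metrics[[metric]]
    stopifnot(is.matrix(m))
    if (is.null(rownames(m)) || !all(manifest$subject_id %in% rownames(m))) {
      stop("metric matrix '", metric, "' must carry subject_id rownames")
    }
    node_names <- colnames(m)
    if (is.null(node_names)) node_names <- paste0("node_", seq_len(ncol(m)))
    ms <- m[schz_ids, , drop = FALSE]
    mt <- m[td_ids, , drop = FALSE]

    node_rows <- compare_columns(ms, mt, unit = "node", names = node_names,
                                 metric = metric)
    comparisons[[length(comparisons) + 1]] <- node_rows

    if (!is.null(mapping)) {
      labels <- if (is.data.frame(mapping)) mapping$rsn_label else mapping
      rsn_s <- t(apply(ms, 1, rsn_aggregate, mapping = labels))
      rsn_t <- t(apply(mt, 1, rsn_aggregate, mapping = labels))
      comparisons[[length(comparisons) + 1]] <-
        compare_columns(rsn_s, rsn_t, unit = "rsn", names = colnames(rsn_s),
                        metric = metric)
    }
    wb_s <- matrix(rowMeans(ms), ncol = 1, dimnames = list(NULL, "whole_brain"))
    wb_t <- matrix(rowMeans(mt), ncol = 1, dimnames = list(NULL, "whole_brain"))
    comparisons[[length(comparisons) + 1]] <-
      compare_columns(wb_s, wb_t, unit = "whole_brain", names = "whole_brain",
                      metric = metric)
  }
  comparisons <- do.call(rbind, comparisons)

  correlations <- correlate_scores(metrics, manifest, schz_ids)
  list(comparisons = comparisons, correlations = correlations, alpha = alpha)
}

compare_columns <- function(ms, mt, unit, names, metric) {
  tests <- lapply(seq_len(ncol(ms)), function(j) two_sample_ttest(ms[, j], mt[, j]))
  p_raw <- vapply(tests, `[[`, numeric(1), "p")
  data.frame(
    unit = unit, name = names, metric = metric,
    mean_schz = vapply(tests, `[[`, numeric(1), "mean_x"),
    sd_schz = vapply(tests, `[[`, numeric(1), "sd_x"),
    mean_td = vapply(tests, `[[`, numeric(1), "mean_y"),
    sd_td = vapply(tests, `[[`, numeric(1), "sd_y"),
    t = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p_raw = p_raw,
    p_fdr = fdr_adjust(p_raw),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

correlate_scores <- function(metrics, manifest, schz_ids) {
  rows <- list()
  for (score in intersect(c("sans", "saps"), names(manifest))) {
    scores <- manifest[[score]][match(schz_ids, manifest$subject_id)]
    keep <- !is.na(scores)
    if (!all(keep)) {
      warning(sum(!keep), " patient(s) missing ", toupper(score),
              " excluded from correlations")
    }
    ids <- schz_ids[keep]
    if (length(ids) < 3) next
    for (metric in names(metrics)) {
      m <- metrics[[metric]][ids, , drop = FALSE]
      node_names <- colnames(m)
      if (is.null(node_names)) node_names <- paste0("node_", seq_len(ncol(m)))
      for (j in seq_len(ncol(m))) {
        if (stats::sd(m[, j]) == 0) next
        ct <- spearman_corr(m[, j], scores[keep])
        rows[[length(rows) + 1]] <- data.frame(
          metric = metric, node = j, name = node_names[j],
          score = toupper(score), rho = ct$rho, p = ct$p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(metric = character(), node = integer(), name = character(),
               score = character(), rho = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
}
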