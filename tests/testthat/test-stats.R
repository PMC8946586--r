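test_that("pooled t-test matches hand computation and symmetries", {
  r <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-12)

  same <- two_sample_ttest(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "zero pooled variance")

  set.seed(61)
  x <- rnorm(8); y <- rnorm(10)
  a <- two_sample_ttest(x, y); b <- two_sample_ttest(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("pooled t-test p-values are uniform under the normal null", {
  set.seed(62)
  p <- replicate(3000, two_sample_ttest(rnorm(10), rnorm(10))$p)
  # exact uniformity of the null p-value distribution implies nominal
  # size at every level; the KS check is sharper than a single rate
  expect_gt(stats::ks.test(p, "punif")$p.value, 1e-3)
})

test_that("BH adjustment matches the step-up computation", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH is monotone and dominates the raw p-values", {
  set.seed(63)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  # re-application is a fixed point once the step-up has flattened the
  # adjusted values
  expect_equal(fdr_adjust(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4))
  expect_equal(fdr_adjust(fdr_adjust(rep(0.2, 5))), rep(0.2, 5))
})

test_that("Spearman correlation matches the rank formula", {
  expect_equal(spearman_corr(1:6, c(2, 4, 6, 8, 10, 12))$rho, 1)
  # sum of squared rank differences = 8 -> rho = 1 - 48/120 = 0.6
  expect_equal(spearman_corr(1:5, c(3, 1, 2, 5, 4))$rho, 0.6)
  set.seed(64)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_corr(x, exp(y))$rho, spearman_corr(x, y)$rho)
  expect_error(spearman_corr(1:5, rep(1, 5)), "constant")
})

test_that("2x2 chi-square is the uncorrected Pearson test", {
  sex <- rbind(c(42, 27), c(38, 12))
  r <- chi_square_2x2(sex)
  expect_equal(r$df, 1)
  expect_equal(round(r$p, 3), 0.083)
  expect_equal(chi_square_2x2(t(sex))$chi2, r$chi2)

  prop <- chi_square_2x2(rbind(c(10, 20), c(5, 10)))
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)

  extreme <- chi_square_2x2(rbind(c(10, 0), c(0, 10)))
  expect_equal(extreme$chi2, 20)
  expect_equal(extreme$p, pchisq(20, 1, lower.tail = FALSE))

  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("layer clustering-sequence correlations have unit diagonal", {
  set.seed(65)
  seqs <- list(slow5 = rnorm(30), slow4 = rnorm(30), slow3 = rnorm(30))
  seqs$dup <- seqs$slow5
  m <- layer_cc_correlation(seqs)
  expect_equal(diag(m), c(slow5 = 1, slow4 = 1, slow3 = 1, dup = 1))
  expect_equal(m["slow5", "dup"], 1)
  expect_equal(m, t(m))

  seqs$flat <- rep(2, 30)
  expect_warning(m2 <- layer_cc_correlation(seqs), "constant")
  expect_true(all(is.na(m2["flat", setdiff(colnames(m2), "flat")])))
  expect_equal(m2["flat", "flat"], 1)
})

test_that("independent sequences correlate weakly", {
  set.seed(66)
  rho <- replicate(300, layer_cc_correlation(list(a = rnorm(90),
                                                  b = rnorm(90)))[1, 2])
  expect_gt(mean(abs(rho) < 0.3), 0.95)
})

test_that("group analysis emits the full bookkeeping and respects scores", {
  set.seed(67)
  n_nodes <- 12
  manifest <- data.frame(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("TD", "SCHZ"), each = 10),
    sans = c(rep(NA, 10), pmax(0, rnorm(10, 35, 10))),
    saps = c(rep(NA, 10), c(pmax(0, rnorm(9, 30, 10)), NA)),
    stringsAsFactors = FALSE
  )
  metrics <- list(
    emd = matrix(rnorm(20 * n_nodes), 20,
                 dimnames = list(manifest$subject_id, NULL)),
    mcc = matrix(rnorm(20 * n_nodes), 20,
                 dimnames = list(manifest$subject_id, NULL))
  )
  mapping <- rep(c("visual", "attention", "subcortical"), each = 4)
  expect_warning(res <- run_group_analysis(metrics, manifest, mapping),
                 "missing SAPS")
  cmp <- res$comparisons
  # 12 nodes + 3 RSNs + whole brain, per metric
  expect_equal(nrow(cmp), 2 * (n_nodes + 3 + 1))
  expect_true(all(cmp$p_fdr >= cmp$p_raw - 1e-15))
  expect_true(all(cmp$df == 18))
  # FDR families are per metric and per scale
  node_emd <- cmp[cmp$unit == "node" & cmp$metric == "emd", ]
  expect_equal(node_emd$p_fdr, fdr_adjust(node_emd$p_raw))
  # correlations are patient-only; one patient lacks SAPS
  expect_equal(nrow(res$correlations), 2 * n_nodes * 2)
  expect_true(all(abs(res$correlations$rho) <= 1))
})
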