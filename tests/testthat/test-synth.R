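test_that("the default cohort reproduces the reference design", {
  cfg <- synth_config()
  expect_equal(cfg$n_regions, 90L)
  expect_equal(cfg$n_timepoints, 142L)
  expect_equal(cfg$tr_seconds, 2)
  co <- synthesize_cohort(synth_config(n_regions = 10, n_timepoints = 110))
  expect_equal(nrow(co$manifest), 119)
  expect_equal(sum(co$manifest$group == "TD"), 69)
  expect_equal(sum(co$manifest$group == "SCHZ"), 50)
  # symptom scores present iff patient, nonnegative
  expect_true(all(is.na(co$manifest$sans[co$manifest$group == "TD"])))
  expect_true(all(co$manifest$sans[co$manifest$group == "SCHZ"] >= 0))
  expect_true(all(!is.na(co$manifest$saps[co$manifest$group == "SCHZ"])))
})

test_that("cohorts are bit-identical given the same config and seed", {
  cfg <- synth_config(n_regions = 8, n_timepoints = 110, n_controls = 3,
                      n_patients = 3, seed = 99)
  a <- synthesize_cohort(cfg)
  b <- synthesize_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$series, b$series)
  c2 <- synthesize_cohort(synth_config(n_regions = 8, n_timepoints = 110,
                                       n_controls = 3, n_patients = 3,
                                       seed = 100))
  expect_false(identical(a$series[[1]], c2$series[[1]]))
})

test_that("zero coupling yields uncorrelated regions", {
  cfg <- synth_config(n_regions = 12, n_timepoints = 120, n_controls = 1,
                      n_patients = 0, within_module_coupling = 0)
  set.seed(71)
  rbar <- replicate(100, {
    r <- pearson_connectivity(synthesize_subject(cfg))
    mean(r[upper.tri(r)])
  })
  expect_lt(abs(mean(rbar)), 0.05)
})

test_that("same-module regions correlate strongly in their band", {
  # two regions sharing a slow4 module, coupling 1, weak noise
  comms <- list(rep(0L, 6), c(1L, 1L, 0L, 0L, 0L, 0L), rep(0L, 6), rep(0L, 6))
  cfg <- synth_config(n_regions = 6, n_timepoints = 120, n_controls = 1,
                      n_patients = 0, band_communities = comms,
                      within_module_coupling = 1, noise_sd = 0.1)
  set.seed(72)
  r_pair <- replicate(50, {
    x <- synthesize_subject(cfg)
    xf <- bandpass(x, 0.027, 0.073, 2)
    cor(xf[1, ], xf[2, ])
  })
  expect_gt(mean(r_pair), 0.8)
})

test_that("zero score coupling leaves scores independent of node metrics", {
  # 20 cohorts x 3 nodes; 25 patients each so the median rho estimator's
  # own noise sits well inside the 0.1 tolerance
  set.seed(73)
  probe_nodes <- c(1, 5, 9)
  rhos <- unlist(lapply(1:20, function(k) {
    cfg <- synth_config(n_regions = 10, n_timepoints = 110, n_controls = 2,
                        n_patients = 25, effect_nodes = 1:3, effect_size = 1,
                        score_coupling = 0, seed = sample.int(1e6, 1))
    co <- synthesize_cohort(cfg)
    pats <- co$manifest$group == "SCHZ"
    emd <- vapply(co$series[pats], function(ts) {
      conns <- lapply(split(multiplex_bands(), seq_len(4)), function(b) {
        pearson_connectivity(bandpass(ts, b$low_hz, b$high_hz, 2))
      })
      node_emd(build_layer_stack(conns, 0.2), probe_nodes)
    }, numeric(length(probe_nodes)))
    apply(emd, 1, function(v) spearman_corr(v, co$manifest$sans[pats])$rho)
  }))
  expect_lt(abs(median(rhos)), 0.1)
})

test_that("the planted EMD effect grows monotonically with effect size", {
  set.seed(74)
  eff <- 1:5
  levels <- c(0, 0.5, 1)
  gaps <- sapply(levels, function(es) {
    mean(replicate(20, {
      cfg <- synth_config(n_regions = 20, n_timepoints = 110, n_controls = 8,
                          n_patients = 8, effect_nodes = eff,
                          effect_type = "degree_rebalance", effect_size = es,
                          seed = sample.int(1e6, 1))
      co <- synthesize_cohort(cfg)
      cfgp <- pipeline_config(include_single_layer = FALSE)
      emd <- t(vapply(co$series, function(ts) {
        subject_metrics(ts, 2, cfgp)$emd_auc
      }, numeric(20)))
      pats <- co$manifest$group == "SCHZ"
      mean(emd[pats, eff]) - mean(emd[!pats, eff])
    }))
  })
  expect_true(all(diff(gaps) >= 0))
  expect_lt(abs(gaps[1]), 0.05)  # no effect at zero effect size
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_regions = 2), "n_regions")
  expect_error(synth_config(n_timepoints = 20), "n_timepoints")
  expect_error(synth_config(n_regions = 10, effect_nodes = 11), "effect_nodes")
  expect_error(synth_config(n_regions = 10, n_timepoints = 80),
               "2 cycles")  # 160 s < 200 s at the 0.01 Hz edge
  expect_error(synth_config(n_regions = 10, n_timepoints = 110,
                            band_communities = list(1:10, 1:10)),
               "one partition per band")
  expect_error(synth_config(n_regions = 10, n_timepoints = 110,
                            band_communities = rep(list(rep(1L, 9)), 4)),
               "partition")
})
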