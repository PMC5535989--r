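test_that("rhythmic label count is exact and output is seed-deterministic", {
  cfg <- simConfig(n_features = 2006L, rhythmic_fraction = 150 / 2006,
                   seed = 7L)
  sim1 <- generateExpressionDataset(cfg)
  sim2 <- generateExpressionDataset(cfg)
  expect_identical(sum(sim1$truth$is_rhythmic), 150L)
  expect_identical(exprValues(sim1$exprs), exprValues(sim2$exprs))
  expect_identical(sim1$truth, sim2$truth)
  sim3 <- generateExpressionDataset(simConfig(n_features = 2006L,
                                              rhythmic_fraction = 150 / 2006,
                                              seed = 8L))
  expect_false(identical(exprValues(sim1$exprs), exprValues(sim3$exprs)))
})

test_that("noiseless rhythmic rows are exact cosines recovered by the fitter", {
  cfg <- simConfig(n_features = 5L, rhythmic_fraction = 1, noise_sd = 0,
                   seed = 11L)
  sim <- generateExpressionDataset(cfg)
  m <- exprValues(sim$exprs)
  t_h <- timesH(sim$exprs)
  tr <- sim$truth
  for (i in seq_len(nrow(m))) {
    curve <- tr$beta_true[i] * cos(tr$omega_true[i] * t_h + tr$phi_true[i])
    expect_equal(m[i, ] - mean(m[i, ]), curve - mean(curve),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  f <- fitParams(fitCosineMatrix(sim$exprs))
  expect_true(all(f$r > 1 - 1e-6))
  expect_lt(max(abs(f$beta - tr$beta_true)), 1e-4)
  expect_lt(max(abs(f$omega - tr$omega_true)), 1e-4)
  dphi <- abs(atan2(sin(f$phi - tr$phi_true), cos(f$phi - tr$phi_true)))
  expect_lt(max(dphi), 1e-4)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(simConfig(n_timepoints = 3L), "n_timepoints")
  expect_error(simConfig(rhythmic_fraction = 1.5), "rhythmic_fraction")
  expect_error(simConfig(dt_hours = 0), "dt_hours")
  expect_error(simConfig(beta_range = c(0.5, 0.05)), "beta_range")
  expect_error(simConfig(beta_range = c(0, 31)), "beta_range")
  expect_error(simConfig(noise_sd = -1), "noise_sd")
  expect_error(simConfig(seed = 1.5), "seed")
})

test_that("parameter draws respect the model boxes across seeds", {
  for (s in c(1L, 12L, 123L)) {
    tr <- generateExpressionDataset(
      simConfig(n_features = 300L, rhythmic_fraction = 0.5, seed = s))$truth
    rhy <- tr[tr$is_rhythmic, ]
    expect_true(all(rhy$omega_true >= 0 & rhy$omega_true <= pi))
    expect_true(all(rhy$beta_true >= 0.05 & rhy$beta_true <= 0.5))
    expect_true(all(rhy$phi_true >= -pi & rhy$phi_true < pi))
    expect_true(all(rhy$phase_group %in% 1:6))
    non <- tr[!tr$is_rhythmic, ]
    expect_true(all(is.na(non$beta_true) & is.na(non$omega_true) &
                      is.na(non$phi_true) & is.na(non$phase_group)))
  }
})

test_that("replicate probe spots share signal and collapse back to features", {
  cfg <- simConfig(n_features = 10L, rhythmic_fraction = 0.5,
                   replicate_probes_per_feature = 30L, noise_sd = 0.05,
                   seed = 4L)
  sim <- generateExpressionDataset(cfg)
  expect_identical(nrow(sim$exprs), 300L)
  expect_identical(nrow(sim$probe_map), 300L)
  collapsed <- collapseProbes(sim$exprs, sim$probe_map)
  expect_identical(nrow(collapsed), 10L)
  expect_identical(rownames(collapsed), sim$truth$feature_id)
})

test_that("entrained clock-gene profiles recover a ~24 h BMAL1 period in antiphase to PER2", {
  cg <- generateClockGeneProfiles("entrained", seed = 21L)
  expect_identical(referenceFeature(cg), "GAPDH")
  rel_b <- deltaDeltaCt(cg, "BMAL1")
  rel_p <- deltaDeltaCt(cg, "PER2")
  tst <- permutationRhythmTest(rel_b$fold_mean, rel_b$time_h,
                               n_perm = 499L, seed = 5L)
  expect_gte(tst$period_h, 22)
  expect_lte(tst$period_h, 26)
  expect_lt(tst$p_value, 0.05)
  # antiphase: log-fold profiles anticorrelated
  expect_lt(cor(log2(rel_b$fold_mean), log2(rel_p$fold_mean)), -0.3)
  # determinism
  cg2 <- generateClockGeneProfiles("entrained", seed = 21L)
  expect_identical(ctData(cg), ctData(cg2))
})

test_that("arrhythmic clock-gene profiles stay flat", {
  cg <- generateClockGeneProfiles("arrhythmic", seed = 9L)
  rel <- deltaDeltaCt(cg, "BMAL1")
  expect_lt(max(abs(log2(rel$fold_mean))), 1)
  tst <- permutationRhythmTest(rel$fold_mean, rel$time_h,
                               n_perm = 199L, seed = 5L)
  expect_gt(tst$p_value, 0.05)
})

test_that("qPCR generator encodes fold changes through the inverse ddCt model", {
  tr <- data.frame(feature_id = c("miR-A", "miR-B"),
                   is_rhythmic = c(TRUE, FALSE),
                   beta_true = c(0.2, NA), omega_true = c(2 * pi / 24, NA),
                   phi_true = c(-0.5, NA), phase_group = c(1L, NA))
  ct <- generateQpcrDataset(tr, n_replicates = 3L, ct_noise_sd = 0,
                            seed = 2L)
  # zero-noise round trip: ddCt recovers the generator's fold series exactly
  rel <- deltaDeltaCt(ct, "miR-A")
  t_h <- rel$time_h
  expected <- 10^(0.2 * (cos(2 * pi / 24 * t_h - 0.5) - cos(-0.5)))
  expect_equal(rel$fold_mean, expected, tolerance = 1e-12)
  expect_true(all(rel$fold_sem == 0))
  # constant-fold feature: target Ct flat over time in every replicate
  d <- ctData(ct)
  for (rp in unique(d$replicate_id)) {
    cts <- d$ct[d$feature_id == "miR-B" & d$replicate_id == rp]
    expect_equal(diff(range(cts)), 0, tolerance = 1e-12)
  }
})

test_that("qPCR generator handles missing tails and rejects impossible ones", {
  tr <- data.frame(feature_id = "miR-A", is_rhythmic = FALSE,
                   beta_true = NA, omega_true = NA, phi_true = NA,
                   phase_group = NA)
  ct <- generateQpcrDataset(tr, missing_tail = 2L, seed = 1L)
  d <- ctData(ct)
  per_rep <- table(d$feature_id, d$replicate_id)["miR-A", ]
  expect_true(all(per_rep == 11L))          # 13-point grid minus 2
  expect_false(any(d$time_h > 40))
  expect_error(generateQpcrDataset(tr, missing_tail = 13L), "missing_tail")
  ct2 <- generateQpcrDataset(tr, missing_tail = 2L, seed = 1L)
  expect_identical(ctData(ct), ctData(ct2))
})
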