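test_that("hypergeometric overlap p matches hand-derived and enumerated values", {
  # N=10, |A|=4, |B|=5, k=3: 66 of the 252 possible draws overlap in >= 3
  setA <- paste0("m", 1:4)
  setB <- paste0("m", c(2, 3, 4, 8, 9))
  ov <- overlapSignificance(setA, setB, universe_size = 10)
  expect_identical(ov$overlap, 3L)
  expect_equal(ov$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(ov$p_value, oracle_hyper_p(10, 4, 5, 3), tolerance = 1e-12)
  # k = 0 -> p = 1 exactly
  ov0 <- overlapSignificance(paste0("a", 1:3), paste0("b", 1:3), 12)
  expect_identical(ov0$p_value, 1)
  # k = |A| <= |B|: single-term tail C(N-|A|, |B|-|A|) / C(N, |B|)
  ovf <- overlapSignificance(paste0("m", 1:3), paste0("m", 1:5), 10)
  expect_equal(ovf$p_value, choose(7, 2) / choose(10, 5), tolerance = 1e-12)
  expect_error(overlapSignificance(paste0("x", 1:9), "x1", universe_size = 5),
               "universe")
})

test_that("hypergeometric p agrees with exhaustive enumeration for small universes", {
  for (N in c(5L, 7L, 9L)) {
    for (a in seq_len(N)) {
      for (b in seq_len(N)) {
        for (k in 0:min(a, b)) {
          p_pkg <- stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE)
          expect_equal(p_pkg, oracle_hyper_p(N, a, b, k), tolerance = 1e-12,
                       info = sprintf("N=%d a=%d b=%d k=%d", N, a, b, k))
        }
      }
    }
  }
})

test_that("overlap p is monotone non-increasing in the observed overlap", {
  N <- 50L; a <- 12L; b <- 20L
  p <- vapply(0:12, function(k)
    stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE), 0)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("venn regions partition the pairwise overlaps", {
  # emulate a 2-in-3 overlap pattern: |A n B| = 11 of which 2 are triple
  A <- c(sprintf("ab%d", 1:9), sprintf("abc%d", 1:2), sprintf("a%d", 1:130))
  B <- c(sprintf("ab%d", 1:9), sprintf("abc%d", 1:2), sprintf("bc%d", 1:9),
         sprintf("b%d", 1:160))
  C <- c(sprintf("abc%d", 1:2), sprintf("bc%d", 1:9), sprintf("c%d", 1:135))
  v <- vennCounts(list(A = A, B = B, C = C))
  cnt <- function(p) v$count[v$region == p]
  expect_identical(cnt("110") + cnt("111"), 11L)   # 9 + 2 pattern
  expect_identical(cnt("011") + cnt("111"), 11L)
  expect_identical(cnt("111"), 2L)
  # regions partition the union
  expect_identical(sum(v$count), length(unique(c(A, B, C))))
  ov <- overlapSignificance(A, B, universe_size = 2006)
  expect_identical(ov$overlap, 11L)
})

test_that("phase clustering recovers planted phase groups", {
  sim <- generateExpressionDataset(simConfig(n_features = 60L,
                                             rhythmic_fraction = 1,
                                             noise_sd = 0.02, seed = 19L))
  fits <- fitCosineMatrix(sim$exprs)
  calls <- classifyRhythmic(fits, rhythmicityThresholds(r_min = 0.5,
                                                        amplitude_min = 0))
  cl <- clusterByPhase(calls, k = 6L)
  truth_grp <- sim$truth$phase_group[match(cl$feature_id,
                                           sim$truth$feature_id)]
  ari <- adjustedRand(cl$cluster, truth_grp)
  expect_gt(ari, 0.9)
  # against the independent implementation
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(cl$cluster, truth_grp),
               tolerance = 1e-12)
})

test_that("degenerate clustering cases behave per contract", {
  calls1 <- data.frame(feature_id = paste0("f", 1:5), is_rhythmic = TRUE,
                       period_h = 24, peak_phase_h = 6, amplitude = 0.2,
                       r = 0.95, omega = 0.26, phi = -1.57)
  cl1 <- clusterByPhase(calls1, k = 1L)
  expect_true(all(cl1$cluster == 1L))
  # two tight antipodal groups split perfectly at k = 2
  calls2 <- data.frame(feature_id = paste0("g", 1:10), is_rhythmic = TRUE,
                       period_h = 24,
                       peak_phase_h = rep(c(0, 12), each = 5) +
                         rep(c(0, 0.1, -0.1, 0.2, -0.2), 2),
                       amplitude = 0.2, r = 0.95, omega = 0.26, phi = 0)
  cl2 <- clusterByPhase(calls2, k = 2L)
  expect_identical(length(unique(cl2$cluster[1:5])), 1L)
  expect_identical(length(unique(cl2$cluster[6:10])), 1L)
  expect_false(cl2$cluster[1] == cl2$cluster[6])
  expect_error(clusterByPhase(calls1, k = 6L), "fewer rhythmic")
})

test_that("cluster assignment is stable under feature reordering", {
  sim <- generateExpressionDataset(simConfig(n_features = 48L,
                                             rhythmic_fraction = 1,
                                             noise_sd = 0.02, seed = 29L))
  calls <- classifyRhythmic(fitCosineMatrix(sim$exprs),
                            rhythmicityThresholds(r_min = 0.5,
                                                  amplitude_min = 0))
  cl <- clusterByPhase(calls, k = 6L)
  set.seed(1)
  perm <- sample.int(nrow(calls))
  cl_p <- clusterByPhase(calls[perm, ], k = 6L)
  m <- match(cl$feature_id, cl_p$feature_id)
  expect_equal(adjustedRand(cl$cluster, cl_p$cluster[m]), 1)
})

test_that("call summaries print truncated two-decimal percentages", {
  mk <- function(n_r, n = 2006L) data.frame(
    feature_id = sprintf("m%04d", seq_len(n)),
    is_rhythmic = seq_len(n) <= n_r)
  res <- summarizeCalls(list(mk(143L), mk(183L), mk(147L)),
                        universe_size = 2006L)
  expect_equal(res$summary$pct_rhythmic, c(7.12, 9.12, 7.32))
  # rounding display differs for 143/2006 (7.1286 -> 7.13)
  res_r <- summarizeCalls(list(mk(143L)), universe_size = 2006L,
                          display = "round")
  expect_equal(res_r$summary$pct_rhythmic, 7.13)
  expect_equal(summarizeCalls(list(mk(0L)),
                              universe_size = 2006L)$summary$pct_rhythmic, 0)
  # overlaps + venn emitted for a trio of datasets
  expect_s3_class(res$overlaps, "data.frame")
  expect_identical(nrow(res$overlaps), 3L)
  expect_identical(sum(res$venn$count), 183L)  # union of nested sets
})

test_that("z-scaling standardizes rows and orders them by cluster then phase", {
  sim <- generateExpressionDataset(simConfig(n_features = 40L,
                                             rhythmic_fraction = 1,
                                             noise_sd = 0.02, seed = 33L))
  calls <- classifyRhythmic(fitCosineMatrix(sim$exprs),
                            rhythmicityThresholds(r_min = 0.5,
                                                  amplitude_min = 0))
  cl <- clusterByPhase(calls, k = 4L)
  z <- zscaleForHeatmap(sim$exprs, calls, cl)
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(z)), tolerance = 1e-12)
  z2 <- zscaleForHeatmap(sim$exprs, calls, cl)
  expect_identical(z, z2)
  ord_cl <- cl$cluster[match(rownames(z), cl$feature_id)]
  expect_true(!is.unsorted(ord_cl))
  # constant rows come back as zeros, with a warning
  m <- rbind(flat = rep(3, 8), wave = cos(0.26 * seq(0, 28, 4)))
  calls2 <- data.frame(feature_id = c("flat", "wave"), is_rhythmic = TRUE,
                       period_h = 24, peak_phase_h = c(1, 2),
                       amplitude = 1, r = 1, omega = 0.26, phi = 0)
  expect_warning(z3 <- zscaleForHeatmap(m, calls2), "zero-variance")
  expect_true(all(z3["flat", ] == 0))
})
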