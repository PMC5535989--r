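test_that("quantile normalization maps columns to rank means with tie handling", {
  m <- matrix(c(1, 3, 2, 4), nrow = 2)
  q <- quantileNormalize(m)
  expect_equal(q, matrix(c(1.5, 3.5, 1.5, 3.5), nrow = 2),
               ignore_attr = TRUE)
  # constant column pair: ties take the mean of the rank means
  m2 <- matrix(c(5, 5, 7, 7), nrow = 2)
  expect_equal(quantileNormalize(m2), matrix(6, 2, 2), ignore_attr = TRUE)
  # identical columns are a fixed point
  m3 <- matrix(rep(c(2, 9, 4), 3), ncol = 3)
  expect_equal(quantileNormalize(m3), m3, ignore_attr = TRUE)
})

test_that("quantile normalization equalizes column multisets and is idempotent", {
  set.seed(31)
  m <- matrix(rexp(80, 1 / 100), nrow = 10)
  q <- quantileNormalize(m)
  ref <- sort(q[, 1])
  for (j in 2:ncol(q)) expect_equal(sort(q[, j]), ref)
  # within-column rank order preserved
  for (j in seq_len(ncol(q))) expect_identical(order(q[, j]), order(m[, j]))
  expect_equal(quantileNormalize(q), q, tolerance = 1e-12)
})

test_that("quantile normalization rejects missing values and single columns", {
  m <- matrix(c(1, NA, 2, 4), nrow = 2)
  expect_error(quantileNormalize(m), "missing")
  expect_error(quantileNormalize(matrix(1:5, ncol = 1)), "2 columns")
})

test_that("log10 transform floors, preserves order, and refuses double application", {
  m <- matrix(c(100, 0.5, 10, 1000), nrow = 2)
  lt <- log10Transform(m)
  expect_equal(lt[1, 1], 2)
  expect_equal(lt[2, 1], 0)        # 0.5 floored to 1
  set.seed(5)
  m2 <- matrix(rexp(60, 1 / 50) + 1, nrow = 6)
  l2 <- log10Transform(m2)
  for (j in seq_len(ncol(m2))) expect_identical(order(l2[, j]), order(m2[, j]))
  x <- matrix(10^seq(0, 3, length.out = 8), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(log10Transform(x), log10(x), ignore_attr = TRUE)
  etc <- ExpressionTimeCourse(m2, times_h = seq(0, 36, by = 4),
                              log_scale = FALSE)
  etc_t <- log10Transform(etc)
  expect_true(isLogScale(etc_t))
  expect_error(log10Transform(etc_t), "already")
})

test_that("probe collapse takes per-timepoint medians by (miRNA, probe) key", {
  t_h <- seq(0, 28, by = 4)
  m <- rbind(matrix(5, 30, 8),                       # 30 identical replicates
             c(1, 1, 1, 1, 1, 1, 1, 1),
             c(2, 2, 2, 2, 2, 2, 2, 2),
             c(100, 100, 100, 100, 100, 100, 100, 100))
  rownames(m) <- c(sprintf("p%02d", 1:30), "q1", "q2", "q3")
  pm <- data.frame(
    probe_id = rownames(m),
    mirna_id = c(rep("miR-X", 30), rep("miR-Y", 3)),
    probe_index = c(rep(1L, 30), rep(1L, 3)))
  out <- collapseProbes(m, pm)
  expect_identical(nrow(out), 2L)
  expect_true(all(out["miR-X", ] == 5))
  expect_true(all(out["miR-Y", ] == 2))    # median of 1, 2, 100
})

test_that("distinct probe sequences of one miRNA stay separate rows", {
  m <- matrix(1:16, nrow = 4,
              dimnames = list(c("a1", "a2", "b1", "b2"), NULL))
  pm <- data.frame(probe_id = rownames(m),
                   mirna_id = c("miR-1", "miR-1", "miR-1", "miR-2"),
                   probe_index = c(1L, 1L, 2L, 1L))
  out <- collapseProbes(m, pm)
  expect_identical(nrow(out), 3L)          # distinct (miRNA, probe) keys
  expect_setequal(rownames(out), c("miR-1_p1", "miR-1_p2", "miR-2"))
})

test_that("unmapped probes abort the collapse with their identifiers", {
  m <- matrix(1:8, nrow = 2, dimnames = list(c("known", "mystery"), NULL))
  pm <- data.frame(probe_id = "known", mirna_id = "miR-1", probe_index = 1L)
  expect_error(collapseProbes(m, pm), "mystery")
})

test_that("expression TSV round trip is lossless, including odd time grids", {
  set.seed(77)
  m <- matrix(rnorm(24) * 1e3, nrow = 4,
              dimnames = list(paste0("feat", 1:4), NULL))
  etc <- ExpressionTimeCourse(m, times_h = c(0, 4, 9, 12.5, 24, 28))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTSV(etc, path)
  back <- readExpressionTSV(path)
  expect_identical(exprValues(back), exprValues(etc))
  expect_identical(timesH(back), timesH(etc))
})

test_that("malformed expression TSVs produce parse errors with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  expect_error(readExpressionTSV(path), "line 1")
  writeLines(c("feature_id\tt0\tt4", "f1\t1\toops"), path)
  expect_error(readExpressionTSV(path), "line 2")
  writeLines(c("feature_id\tt0\tt4", "f1\t1\t2", "f1\t3\t4"), path)
  expect_error(readExpressionTSV(path), "duplicated feature_id")
  writeLines(c("wrong\theader", "f1\t1"), path)
  expect_error(readExpressionTSV(path), "header")
})

test_that("Ct TSV round trip preserves data, reference and baseline", {
  cg <- generateClockGeneProfiles("entrained", seed = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCtTSV(cg, path)
  back <- readCtTSV(path)
  expect_equal(ctData(back)$ct, ctData(cg)$ct, tolerance = 1e-12)
  expect_identical(referenceFeature(back), "GAPDH")
  expect_identical(baselineTime(back), 0)
})
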