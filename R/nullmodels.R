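.randomizeCore <- function(m, kind, n_blocks) {
  kind <- match.arg(kind, c("TL", "RW", "CW", "RCW", "RCWB"))
  nr <- nrow(m); nc <- ncol(m)
  rw <- function(x) {
    t(apply(x, 1L, sample))
  }
  cw <- function(x) {
    apply(x, 2L, sample)
  }
  out <- switch(kind,
    TL = m[, sample.int(nc), drop = FALSE],
    RW = rw(m),
    CW = cw(m),
    RCW = cw(rw(m)),
    RCWB = {
      if (n_blocks < 2L || n_blocks > nc) {
        stop("'n_blocks' must be >= 2 and <= the column count")
      }
      # contiguous blocks along the time axis, earlier blocks larger
      sizes <- rep(nc %/% n_blocks, n_blocks)
      extra <- nc %% n_blocks
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      blocks <- split(seq_len(nc), rep(seq_len(n_blocks), sizes))
      res <- m
      for (b in blocks) {
        sub <- m[, b, drop = FALSE]
        res[, b] <- if (length(b) == 1L) cw(sub) else cw(rw(sub))
      }
      res
    })
  dimnames(out) <- dimnames(m)
  out
}

#' @rdname randomizeMatrix
#' @export
setMethod("randomizeMatrix", "matrix", function(x, kind, seed, n_blocks = 2L) {
  .assertFiniteMatrix(x, "input to randomizeMatrix")
  .withSeed(seed, .randomizeCore(x, kind, as.integer(n_blocks)))
})

#' @rdname randomizeMatrix
#' @export
setMethod("randomizeMatrix", "ExpressionTimeCourse",
          function(x, kind, seed, n_blocks = 2L) {
  .replaceValues(x, randomizeMatrix(exprValues(x), kind, seed, n_blocks))
})

#' Fit an ensemble of randomized null matrices
#'
#' Convenience wrapper: draws \code{n_reps} randomized copies of the matrix
#' under one scheme (replicate k uses derived seed \code{seed + k - 1}),
#' fits the cosine model to each, and pools the fits.
#'
#' @param x matrix or \code{\link{ExpressionTimeCourse}}.
#' @param kind randomization scheme (see \code{\link{randomizeMatrix}}).
#' @param seed integer root seed.
#' @param n_reps number of randomized replicates (default 1).
#' @param n_blocks blocks for RCWB.
#' @param ... passed to \code{\link{fitCosineMatrix}}.
#' @return A \code{\link{CosineFitSet}} with \code{n_reps * nrow(x)} rows.
#' @export
nullFitEnsemble <- function(x, kind, seed, n_reps = 1L, n_blocks = 2L, ...) {
  times <- if (methods::is(x, "ExpressionTimeCourse")) timesH(x) else NULL
  fits <- lapply(seq_len(n_reps), function(k) {
    null <- randomizeMatrix(x, kind, seed = seed + k - 1L, n_blocks = n_blocks)
    fitCosineMatrix(null, times_h = times, ...)
  })
  if (n_reps == 1L) return(fits[[1L]])
  all_fits <- do.call(rbind, lapply(seq_along(fits), function(k) {
    f <- fits[[k]]@fits
    f$feature_id <- sprintf("%s_rep%d", f$feature_id, k)
    f
  }))
  methods::new("CosineFitSet", fits = all_fits,
               fitted = do.call(rbind, lapply(fits, fittedCurves)),
               times_h = fits[[1L]]@times_h)
}

#' Compare rhythmicity-feature distributions of experimental vs null fits
#'
#' Two-sample Kolmogorov-Smirnov comparison of the cosine correlation r,
#' angular frequency omega (rad/h) and peak phase (hours, the first peak
#' time of the fitted cosine — the scale rhythm phases are reported on)
#' between experimental and randomized-data fits, plus the proportion of
#' fits with omega below \code{omega_threshold} (features too slow to be
#' called rhythmic). Degenerate fits (undefined omega/phi) are dropped from
#' the corresponding comparison.
#'
#' @param exp_fits,null_fits \code{\link{CosineFitSet}} objects (non-empty).
#' @param omega_threshold rad/h cutoff for the slow-frequency proportion
#'   (default 0.22, the lower classification bound).
#' @return data.frame with one row per feature-statistic (r, omega,
#'   phase_h): KS statistic and p-value, plus columns
#'   \code{frac_omega_below_exp}, \code{frac_omega_below_null} and
#'   \code{n_exp}, \code{n_null}.
#' @export
compareNull <- function(exp_fits, null_fits, omega_threshold = 0.22) {
  stopifnot(methods::is(exp_fits, "CosineFitSet"),
            methods::is(null_fits, "CosineFitSet"))
  fe <- as.data.frame(exp_fits@fits)
  fn <- as.data.frame(null_fits@fits)
  if (nrow(fe) == 0L || nrow(fn) == 0L) {
    stop("fit sets must be non-empty")
  }
  peak_h <- function(f) {
    ok <- !is.na(f$omega) & f$omega > 0 & !is.na(f$phi)
    ((-f$phi[ok]) %% (2 * pi)) / f$omega[ok]
  }
  ks1 <- function(a, b) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    kt <- suppressWarnings(stats::ks.test(a, b))
    c(stat = unname(kt$statistic), p = unname(kt$p.value))
  }
  ks_r <- ks1(fe$r, fn$r)
  ks_w <- ks1(fe$omega, fn$omega)
  ks_p <- ks1(peak_h(fe), peak_h(fn))
  data.frame(
    feature = c("r", "omega", "phase_h"),
    ks_stat = c(ks_r["stat"], ks_w["stat"], ks_p["stat"]),
    ks_p = c(ks_r["p"], ks_w["p"], ks_p["p"]),
    frac_omega_below_exp = mean(fe$omega < omega_threshold, na.rm = TRUE),
    frac_omega_below_null = mean(fn$omega < omega_threshold, na.rm = TRUE),
    n_exp = nrow(fe),
    n_null = nrow(fn),
    row.names = NULL)
}
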