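#' Delta-delta-Ct relative quantification
#'
#' Computes, separately within each biological replicate,
#' \eqn{\Delta Ct(t) = Ct_{target}(t) - Ct_{ref}(t)},
#' \eqn{\Delta\Delta Ct(t) = \Delta Ct(t) - \Delta Ct(baseline)} and the
#' fold change \eqn{2^{-\Delta\Delta Ct(t)}} (amplification efficiency fixed
#' at 2), then averages fold changes across replicates and reports the SEM
#' per timepoint. Fold change at the baseline time is exactly 1 in every
#' replicate by construction. Timepoints missing from the table (e.g. an
#' unmeasured tail) are simply absent from the result, never zero-filled.
#'
#' @param table a \code{\link{CtTable}}.
#' @param target feature id to quantify.
#' @param reference_feature normalizer id; defaults to the table's reference.
#' @param baseline_time baseline hours; defaults to the table's baseline.
#' @return data.frame with feature_id, time_h, fold_mean, fold_sem,
#'   n_replicates; attributes \code{normalizer}, \code{baseline_time} and
#'   \code{replicate_folds} (the per-replicate long table).
#' @export
deltaDeltaCt <- function(table, target,
                         reference_feature = referenceFeature(table),
                         baseline_time = baselineTime(table)) {
  stopifnot(methods::is(table, "CtTable"))
  d <- ctData(table)
  tgt <- d[d$feature_id == target, , drop = FALSE]
  ref <- d[d$feature_id == reference_feature, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("target '", target, "' not present in the table")
  if (nrow(ref) == 0L) {
    stop("reference '", reference_feature, "' not present in the table")
  }
  i <- match(paste(tgt$replicate_id, tgt$time_h),
             paste(ref$replicate_id, ref$time_h))
  if (anyNA(i)) {
    miss <- tgt[is.na(i), c("replicate_id", "time_h")]
    stop("reference missing at populated (replicate, time): ",
         paste(sprintf("(%s, %g h)", miss$replicate_id, miss$time_h),
               collapse = ", "))
  }
  dct <- tgt$ct - ref$ct[i]
  base_key <- match(tgt$replicate_id,
                    tgt$replicate_id[tgt$time_h == baseline_time])
  base_dct <- dct[tgt$time_h == baseline_time][base_key]
  if (anyNA(base_dct)) {
    stop("baseline time ", baseline_time, " h not populated in replicate(s): ",
         paste(unique(tgt$replicate_id[is.na(base_dct)]), collapse = ", "))
  }
  fold <- 2^(-(dct - base_dct))
  rep_folds <- data.frame(feature_id = target,
                          replicate_id = tgt$replicate_id,
                          time_h = tgt$time_h, fold = fold,
                          stringsAsFactors = FALSE)
  agg <- lapply(split(rep_folds, rep_folds$time_h), function(g) {
    data.frame(feature_id = target, time_h = g$time_h[1],
               fold_mean = mean(g$fold),
               fold_sem = if (nrow(g) > 1)
                 stats::sd(g$fold) / sqrt(nrow(g)) else 0,
               n_replicates = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "normalizer") <- reference_feature
  attr(out, "baseline_time") <- baseline_time
  attr(out, "replicate_folds") <- rep_folds
  out
}

# best cosine correlation over a period grid, vectorized over matrix rows;
# the statistic behind the permutation rhythm test
.maxCosineRGrid <- function(Y, times, periods) {
  Yc <- Y - rowMeans(Y)
  best_r <- rep(-Inf, nrow(Y))
  best_period <- rep(NA_real_, nrow(Y))
  for (p in periods) {
    omega <- 2 * pi / p
    X <- .centeredBasis(omega, times)
    cf <- .boundedCoef(X, t(Yc))           # 2 x n
    fc <- X %*% cf                         # T x n, mean-zero fitted curves
    num <- colSums(fc * t(Yc))
    den <- sqrt(colSums(fc^2) * rowSums(Yc^2))
    r <- ifelse(den > 0, num / den, 0)
    gain <- r > best_r
    best_r[gain] <- r[gain]
    best_period[gain] <- p
  }
  best_r[!is.finite(best_r)] <- 0
  list(r = best_r, period_h = best_period)
}

#' Permutation test for rhythmicity of a fold-change series
#'
#' A documented substitute for meta-analytic rhythm-detection packages
#' (which are not re-implemented here): the observed statistic is the best
#' cosine correlation r* over a grid of candidate periods
#' (\code{period_range}, default 20-28 h in \code{period_step} increments);
#' the null distribution is r* recomputed on \code{n_perm} random
#' time-shuffles of the series, and
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n\_perm)}. The statistic is
#' scale-free, so the p-value is invariant to positive rescaling of the
#' series.
#'
#' @param series numeric vector of fold-change means (>= 8 timepoints).
#' @param times_h matching time grid in hours.
#' @param n_perm number of permutations (default 2000).
#' @param seed integer seed for the permutations.
#' @param period_range candidate period window in hours (default c(20, 28)).
#' @param period_step grid step in hours (default 0.25; the grid contains
#'   24 h exactly).
#' @return list with \code{p_value}, \code{period_h} (best-fitting period of
#'   the observed series), \code{r_obs} and \code{n_perm}.
#' @export
permutationRhythmTest <- function(series, times_h, n_perm = 2000L, seed = 1L,
                                  period_range = c(20, 28),
                                  period_step = 0.25) {
  if (length(series) < 8L) stop("at least 8 timepoints are required")
  if (length(series) != length(times_h)) {
    stop("'series' and 'times_h' lengths differ")
  }
  if (anyNA(series) || !all(is.finite(series))) {
    stop("'series' contains missing or non-finite values")
  }
  periods <- seq(period_range[1], period_range[2], by = period_step)
  obs <- .maxCosineRGrid(matrix(series, nrow = 1), times_h, periods)
  perms <- .withSeed(seed, {
    t(vapply(seq_len(n_perm), function(i) series[sample.int(length(series))],
             numeric(length(series))))
  })
  null_r <- .maxCosineRGrid(perms, times_h, periods)$r
  p <- (1 + sum(null_r >= obs$r)) / (1 + n_perm)
  list(p_value = p, period_h = obs$period_h, r_obs = obs$r,
       n_perm = as.integer(n_perm))
}
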