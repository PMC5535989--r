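#' Rhythmicity classification thresholds
#'
#' The restrictive thresholds used to call a feature rhythmic from its
#' cosine fit: cosine correlation r strictly above \code{r_min}, angular
#' frequency omega inside the closed \code{omega_range} (rad/h), and
#' amplitude beta strictly above \code{amplitude_min} (log10 scale).
#' The defaults are r > 0.82, omega in [0.22, 0.29] (periods of roughly
#' 21.7-28.6 h) and beta > 0.045.
#'
#' @param r_min minimum cosine correlation (strict), in [0, 1].
#' @param omega_range inclusive angular-frequency window, within [0, pi].
#' @param amplitude_min minimum amplitude (strict), >= 0.
#' @return a list of class \code{RhythmicityThresholds}.
#' @export
rhythmicityThresholds <- function(r_min = 0.82, omega_range = c(0.22, 0.29),
                                  amplitude_min = 0.045) {
  stopifnot(length(r_min) == 1L, r_min >= 0, r_min <= 1,
            length(omega_range) == 2L, omega_range[1] <= omega_range[2],
            omega_range[1] >= 0, omega_range[2] <= pi,
            length(amplitude_min) == 1L, amplitude_min >= 0)
  structure(list(r_min = r_min, omega_range = as.numeric(omega_range),
                 amplitude_min = amplitude_min),
            class = "RhythmicityThresholds")
}

# profiled least squares at a fixed omega: the model
# beta*cos(omega*t + phi) = a*cos(omega*t) + b*sin(omega*t) is linear in
# (a, b), so amplitude and phase are solved exactly per omega node. The
# constant (mesor) is projected out of data and basis alike, i.e. the fit
# matches the series shape up to an additive level.
.centeredBasis <- function(omega, times) {
  X <- cbind(cos(omega * times), sin(omega * times))
  X - rep(colMeans(X), each = length(times))
}

# Bounded coefficient solve at one omega for all rows of tY (T x n): 2x2
# normal equations, with exact handling of the amplitude box hypot(a, b) <=
# beta_max. Near aliased frequencies on uniform grids the sine column almost
# vanishes and the unconstrained solution blows up; rows whose unconstrained
# norm exceeds the box get the norm-constrained least-squares solution
# (ridge coefficients with the multiplier chosen so the norm sits on the
# boundary). Returns a 2 x n coefficient matrix. Used identically by the
# grid stage, the 1-D refinement and the finalization so all stages
# optimize one objective.
.boundedCoef <- function(Xc, tY, beta_max = 30) {
  n <- ncol(tY)
  xx <- sum(Xc[, 1]^2); yy <- sum(Xc[, 2]^2); xy <- sum(Xc[, 1] * Xc[, 2])
  c1 <- as.numeric(crossprod(Xc[, 1], tY))
  c2 <- as.numeric(crossprod(Xc[, 2], tY))
  det <- xx * yy - xy * xy
  a <- rep(0, n); b <- rep(0, n)
  if (det > 1e-10 * max(xx * yy, 1e-300)) {
    a <- (yy * c1 - xy * c2) / det
    b <- (xx * c2 - xy * c1) / det
    bad <- sqrt(a^2 + b^2) > beta_max
  } else {
    bad <- rep(TRUE, n)
  }
  if (any(bad)) {
    e <- eigen(matrix(c(xx, xy, xy, yy), 2L), symmetric = TRUE)
    d <- pmax(e$values, 0)
    l0 <- 1e-12 * max(d[1], 1)
    for (i in which(bad)) {
      q <- as.numeric(crossprod(e$vectors, c(c1[i], c2[i])))
      excess <- function(l) sum((q / (d + l))^2) - beta_max^2
      if (excess(l0) <= 0) {
        lam <- l0          # minimum-norm solution already inside the box
      } else {
        hi <- sqrt(sum(q^2)) / beta_max
        while (excess(hi) > 0) hi <- hi * 2
        lam <- stats::uniroot(excess, c(l0, hi), tol = 1e-12)$root
      }
      cf <- e$vectors %*% (q / (d + lam))
      h <- sqrt(sum(cf^2))
      if (h > beta_max) cf <- cf * (beta_max / h)   # fp overshoot of the box
      a[i] <- cf[1]; b[i] <- cf[2]
    }
  }
  rbind(a, b, deparse.level = 0)
}

# scalar profiled SSE used by the 1-D refinement
.profileSSE <- function(yc, times, omega) {
  Xc <- .centeredBasis(omega, times)
  cf <- .boundedCoef(Xc, matrix(yc, ncol = 1))
  sum((yc - Xc %*% cf)^2)
}

.omegaGrid <- function(omega_range, n) {
  lo <- omega_range[1]; hi <- omega_range[2]
  stopifnot(lo >= 0, hi <= pi, lo < hi, n >= 2L)
  if (lo <= 0) seq(lo, hi, length.out = n + 1L)[-1L]
  else seq(lo, hi, length.out = n)
}

# core multi-start engine over a centered matrix; returns per-row optima.
# Stage 1 evaluates the profiled SSE for all rows at every omega node
# (vectorized); stage 2 refines the few best basins per row by 1-D
# optimization, breaking SSE ties toward smaller omega.
.fitCentered <- function(Yc, times, omegas, refine = TRUE,
                         max_basins = 12L) {
  n <- nrow(Yc); K <- length(omegas)
  sse <- matrix(NA_real_, n, K)
  tY <- t(Yc)
  for (k in seq_len(K)) {
    X <- .centeredBasis(omegas[k], times)
    cf <- .boundedCoef(X, tY)
    sse[, k] <- colSums((tY - X %*% cf)^2)
  }
  omega_hat <- sse_hat <- numeric(n)
  for (i in seq_len(n)) {
    s <- sse[i, ]
    yc <- Yc[i, ]
    # candidate basins: local minima of the profiled SSE over the grid
    left <- c(Inf, s[-K]); right <- c(s[-1], Inf)
    loc <- which(s <= left & s <= right)
    if (refine && length(loc) > 1L) {
      # refine every basin whose grid value is within 10% of the series
      # energy of the best node: within-basin refinement can improve the
      # SSE by more than the gap between basin node values, so pruning
      # must keep a wide margin (capped at max_basins deepest)
      margin <- 0.1 * sum(yc^2)
      keep <- loc[s[loc] <= min(s[loc]) + margin]
      if (length(keep) > max_basins) {
        cut <- sort(s[keep])[max_basins]
        keep <- keep[s[keep] <= cut + 1e-9 * (1 + abs(cut))]
      }
      loc <- keep
    }
    cand_w <- omegas[loc]; cand_s <- s[loc]
    if (refine) {
      for (j in seq_along(loc)) {
        k <- loc[j]
        lo <- if (k > 1L) omegas[k - 1L] else max(omegas[1L] / 2, 1e-6)
        hi <- if (k < K) omegas[k + 1L] else omegas[K]
        if (hi > lo) {
          opt <- stats::optimize(.profileSSE, lower = lo, upper = hi,
                                 yc = yc, times = times,
                                 tol = .Machine$double.eps^0.5)
          cand_w <- c(cand_w, opt$minimum); cand_s <- c(cand_s, opt$objective)
        }
      }
    }
    best <- min(cand_s)
    eps <- 1e-7 * max(best, 1e-12) + 1e-12
    near <- which(cand_s <= best + eps)
    pick <- near[which.min(cand_w[near])]   # ties broken by smaller omega
    omega_hat[i] <- cand_w[pick]; sse_hat[i] <- cand_s[pick]
  }
  list(omega = omega_hat, sse = sse_hat)
}

# finalize one row: coefficients, bounds, canonical phase, fitted curve, r
.finalizeFit <- function(yc, times, omega) {
  X <- .centeredBasis(omega, times)
  cf <- .boundedCoef(X, matrix(yc, ncol = 1))
  a <- cf[1, 1]; b <- cf[2, 1]
  beta <- min(sqrt(a^2 + b^2), 30)   # fp rounding at the box boundary
  phi <- if (beta > 0) .canonicalPhase(atan2(-b, a)) else NA_real_
  fitted <- as.numeric(X %*% c(a, b))
  r <- if (beta <= 1e-12 || stats::sd(fitted) == 0 || stats::sd(yc) == 0) 0
       else stats::cor(fitted, yc)
  list(beta = beta, phi = phi, fitted = fitted, r = r,
       sse = sum((yc - fitted)^2))
}

#' Fit the bounded cosine model to every feature of a time course
#'
#' Fits \eqn{g = \beta \cos(\omega t + \phi)} to each mean-centered series
#' by bounded least squares with parameter boxes \eqn{\beta \in [0, 30]},
#' \eqn{\omega \in [0, \pi]} rad/h and \eqn{\phi} canonicalized to
#' \eqn{[-\pi, \pi)}. For each fixed omega the model is linear in
#' \eqn{(\beta\cos\phi, -\beta\sin\phi)}, so amplitude and phase are solved
#' in closed form; the search multi-starts over \code{n_omega_starts} omega
#' nodes and locally refines every basin, taking the smallest SSE and
#' breaking ties toward smaller omega. The cosine correlation r is the
#' Pearson correlation between the fitted curve and the centered data;
#' degenerate fits (beta = 0, or zero-variance input) report r = 0.
#'
#' @param x an \code{\link{ExpressionTimeCourse}} or numeric matrix
#'   (features x timepoints) with at least 4 finite values per row.
#' @param times_h time grid in hours (taken from \code{x} when it is an
#'   \code{ExpressionTimeCourse}); strictly increasing.
#' @param n_omega_starts number of omega start nodes spanning
#'   \code{omega_range} (default 96; with phase profiled per node the omega
#'   grid carries the whole start budget).
#' @param n_phi_starts retained for interface compatibility; the profiled
#'   solver obtains phi in closed form per omega node, so phi starts are
#'   not needed.
#' @param omega_range search window for omega, default the full [0, pi] box.
#' @param refine locally refine each SSE basin with 1-D optimization
#'   (default TRUE).
#' @return A \code{\link{CosineFitSet}}.
#' @examples
#' t <- seq(0, 28, by = 4)
#' y <- 0.3 * cos(0.2618 * t - 1.0)
#' fitParams(fitCosine(y, t))
#' @export
fitCosineMatrix <- function(x, times_h = NULL, n_omega_starts = 96L,
                            n_phi_starts = 8L, omega_range = c(0, pi),
                            refine = TRUE) {
  if (methods::is(x, "ExpressionTimeCourse")) {
    times_h <- timesH(x)
    m <- exprValues(x)
  } else {
    m <- as.matrix(x)
    if (is.null(times_h)) stop("'times_h' is required for matrix input")
    if (is.null(rownames(m))) {
      rownames(m) <- sprintf("feature_%04d", seq_len(nrow(m)))
    }
  }
  times_h <- as.numeric(times_h)
  if (length(times_h) != ncol(m)) {
    stop("'times_h' length must match the number of columns")
  }
  if (ncol(m) < 4L) stop("at least 4 timepoints are required")
  if (any(diff(times_h) <= 0)) stop("'times_h' must be strictly increasing")
  .assertFiniteMatrix(m, "input to fitCosineMatrix")

  mean_level <- rowMeans(m)
  Yc <- m - mean_level
  const <- apply(Yc, 1L, function(z) all(abs(z) < 1e-300) || stats::sd(z) == 0)
  if (any(const)) {
    warning(sum(const), " constant series: returning beta = 0, r = 0")
  }

  n <- nrow(m); Tn <- ncol(m)
  beta <- r <- sse <- numeric(n)
  omega <- phi <- rep(NA_real_, n)
  fitted <- matrix(0, n, Tn, dimnames = list(rownames(m), colnames(m)))

  live <- which(!const)
  if (length(live) > 0) {
    omegas <- .omegaGrid(omega_range, as.integer(n_omega_starts))
    opt <- .fitCentered(Yc[live, , drop = FALSE], times_h, omegas, refine)
    for (j in seq_along(live)) {
      i <- live[j]
      fin <- .finalizeFit(Yc[i, ], times_h, opt$omega[j])
      beta[i] <- fin$beta; phi[i] <- fin$phi; r[i] <- fin$r
      sse[i] <- fin$sse; fitted[i, ] <- fin$fitted
      omega[i] <- if (fin$beta > 1e-12) opt$omega[j] else NA_real_
    }
  }
  fits <- S4Vectors::DataFrame(feature_id = rownames(m), beta = beta,
                               omega = omega, phi = phi, r = r, sse = sse,
                               mean_level = mean_level, row.names = NULL)
  methods::new("CosineFitSet", fits = fits, fitted = fitted,
               times_h = times_h)
}

#' @rdname fitCosineMatrix
#' @param series numeric vector, one feature's expression over
#'   \code{times_h}.
#' @export
fitCosine <- function(series, times_h, n_omega_starts = 96L,
                      n_phi_starts = 8L, omega_range = c(0, pi),
                      refine = TRUE) {
  if (length(series) < 4L) stop("at least 4 points are required")
  if (anyNA(series) || !all(is.finite(series))) {
    stop("'series' contains missing or non-finite values")
  }
  m <- matrix(series, nrow = 1, dimnames = list("series", NULL))
  fitCosineMatrix(m, times_h = times_h, n_omega_starts = n_omega_starts,
                  n_phi_starts = n_phi_starts, omega_range = omega_range,
                  refine = refine)
}

#' Convert angular frequency to period, and phase to peak time
#'
#' \code{omegaToPeriodH} returns the period 2*pi/omega in hours;
#' \code{phaseToPeakH} returns the first non-negative peak time
#' \code{((-phi) mod 2*pi) / omega} of \eqn{\cos(\omega t + \phi)}.
#'
#' @param omega angular frequency in rad/h, > 0.
#' @param phi phase in radians.
#' @return hours.
#' @examples
#' omegaToPeriodH(2 * pi / 24)  # 24
#' phaseToPeakH(2 * pi / 24, 0) # peak at t = 0
#' @export
omegaToPeriodH <- function(omega) {
  if (any(!is.finite(omega) | omega <= 0)) {
    stop("'omega' must be > 0 (no finite period otherwise)")
  }
  2 * pi / omega
}

#' @rdname omegaToPeriodH
#' @export
phaseToPeakH <- function(omega, phi) {
  if (any(!is.finite(omega) | omega <= 0)) {
    stop("'omega' must be > 0")
  }
  ((-phi) %% (2 * pi)) / omega
}

#' Classify features as rhythmic from their cosine fits
#'
#' A feature is called rhythmic when its cosine correlation exceeds
#' \code{r_min} (strictly), its angular frequency lies inside the closed
#' \code{omega_range}, and its amplitude exceeds \code{amplitude_min}
#' (strictly). Degenerate fits (omega undefined) are never rhythmic.
#'
#' @param fits a \code{\link{CosineFitSet}}.
#' @param thresholds a \code{\link{rhythmicityThresholds}} object.
#' @return data.frame with one row per feature: feature_id, is_rhythmic,
#'   period_h (2*pi/omega), peak_phase_h (first peak time in [0, period)),
#'   amplitude (= beta), r, omega, phi.
#' @export
classifyRhythmic <- function(fits, thresholds = rhythmicityThresholds()) {
  stopifnot(methods::is(fits, "CosineFitSet"),
            inherits(thresholds, "RhythmicityThresholds"))
  f <- as.data.frame(fits@fits)
  ok <- !is.na(f$omega) & f$omega > 0
  period <- ifelse(ok, 2 * pi / f$omega, NA_real_)
  peak <- ifelse(ok & !is.na(f$phi), ((-f$phi) %% (2 * pi)) / f$omega,
                 NA_real_)
  call <- ok &
    f$r > thresholds$r_min &
    f$omega >= thresholds$omega_range[1] &
    f$omega <= thresholds$omega_range[2] &
    f$beta > thresholds$amplitude_min
  data.frame(feature_id = f$feature_id,
             is_rhythmic = call,
             period_h = period,
             peak_phase_h = peak,
             amplitude = f$beta,
             r = f$r,
             omega = f$omega,
             phi = f$phi,
             stringsAsFactors = FALSE)
}
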