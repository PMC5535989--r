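#' Generate a synthetic expression time course with ground truth
#'
#' Forward-simulates a feature x timepoint log10 expression matrix with the
#' statistical structure the rhythmicity analysis assumes: a rhythmic subset
#' follows \eqn{g = \beta \cos(\omega t + \phi)} around a per-feature
#' baseline with i.i.d. Gaussian noise; the remaining features are baseline
#' plus noise (optionally a smooth AR(1) drift). Acrophases are drawn from
#' \code{n_phase_groups} equally spaced centres with small jitter so phase
#' clusters are recoverable downstream.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param output_scale \code{"log10"} (default) returns the simulated log10
#'   values directly; \code{"raw"} returns \code{10^values} so the full
#'   quantile-normalize / log10 / collapse preprocessing chain can be
#'   exercised.
#' @return A list with elements \describe{
#'   \item{exprs}{\code{\link{ExpressionTimeCourse}} with
#'     \code{n_features * replicate_probes_per_feature} rows (replicate
#'     spots share the feature signal but get independent noise);}
#'   \item{truth}{data.frame with feature_id, is_rhythmic, beta_true,
#'     omega_true, phi_true, phase_group (NA sentinels for non-rhythmic
#'     rows); exactly \code{round(n_features * rhythmic_fraction)} rows are
#'     rhythmic;}
#'   \item{probe_map}{data.frame (probe_id, mirna_id, probe_index) mapping
#'     replicate spots back to features for \code{\link{collapseProbes}}.}
#' }
#' Identical configs (including seed) give bit-identical output.
#' @examples
#' sim <- generateExpressionDataset(simConfig(n_features = 20, seed = 7))
#' sum(sim$truth$is_rhythmic)
#' @export
generateExpressionDataset <- function(config,
                                      output_scale = c("log10", "raw")) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  output_scale <- match.arg(output_scale)

  nf <- config@n_features
  nt <- config@n_timepoints
  times <- (seq_len(nt) - 1) * config@dt_hours
  n_rhythmic <- round(nf * config@rhythmic_fraction)
  nrep <- config@replicate_probes_per_feature

  .withSeed(config@seed, {
    feature_id <- sprintf("feat%05d", seq_len(nf))
    is_rhythmic <- rep(FALSE, nf)
    is_rhythmic[sample.int(nf, n_rhythmic)] <- TRUE

    # baseline: background component with an optional expressed right tail
    expressed <- stats::runif(nf) < config@expressed_fraction
    baseline <- stats::rnorm(nf, config@baseline_mean, config@baseline_sd)
    baseline[expressed] <- stats::rnorm(sum(expressed),
                                        config@baseline_mean + config@expressed_shift,
                                        config@expressed_sd)

    beta_true <- omega_true <- phi_true <- rep(NA_real_, nf)
    phase_group <- rep(NA_integer_, nf)
    if (n_rhythmic > 0) {
      idx <- which(is_rhythmic)
      beta_true[idx] <- stats::runif(n_rhythmic, config@beta_range[1],
                                     config@beta_range[2])
      om <- stats::rnorm(n_rhythmic, config@omega_center, config@omega_sd)
      om <- pmin(pmax(om, 0), pi)          # truncate to the omega box
      omega_true[idx] <- om
      phase_group[idx] <- sample.int(config@n_phase_groups, n_rhythmic,
                                     replace = TRUE)
      centers <- -pi + 2 * pi * (seq_len(config@n_phase_groups) - 0.5) /
        config@n_phase_groups
      phi_true[idx] <- .canonicalPhase(
        centers[phase_group[idx]] +
          stats::rnorm(n_rhythmic, 0, config@phase_jitter_sd))
    }

    signal <- matrix(rep(baseline, nt), nrow = nf)
    if (n_rhythmic > 0) {
      idx <- which(is_rhythmic)
      signal[idx, ] <- signal[idx, ] +
        beta_true[idx] * cos(outer(omega_true[idx], times) + phi_true[idx])
    }
    if (config@ar1_drift) {
      idx0 <- which(!is_rhythmic)
      if (length(idx0) > 0) {
        drift <- matrix(0, length(idx0), nt)
        drift[, 1] <- stats::rnorm(length(idx0), 0, config@ar1_sd)
        for (j in seq_len(nt - 1) + 1) {
          drift[, j] <- config@ar1_rho * drift[, j - 1] +
            stats::rnorm(length(idx0), 0, config@ar1_sd)
        }
        signal[idx0, ] <- signal[idx0, ] + drift
      }
    }

    # replicate probe spots: same underlying signal, independent noise
    row_of <- rep(seq_len(nf), each = nrep)
    values <- signal[row_of, , drop = FALSE] +
      matrix(stats::rnorm(nf * nrep * nt, 0, config@noise_sd),
             nrow = nf * nrep)
    probe_id <- if (nrep == 1L) feature_id else
      sprintf("%s_r%02d", feature_id[row_of], rep(seq_len(nrep), nf))
    rownames(values) <- probe_id

    truth <- data.frame(feature_id = feature_id,
                        is_rhythmic = is_rhythmic,
                        beta_true = beta_true,
                        omega_true = omega_true,
                        phi_true = phi_true,
                        phase_group = phase_group,
                        stringsAsFactors = FALSE)
    probe_map <- data.frame(probe_id = probe_id,
                            mirna_id = feature_id[row_of],
                            probe_index = 1L,
                            stringsAsFactors = FALSE)
    if (output_scale == "raw") values <- 10^values
    list(exprs = ExpressionTimeCourse(values, times_h = times,
                                      log_scale = output_scale == "log10"),
         truth = truth,
         probe_map = probe_map)
  })
}

#' Simulate clock-gene qPCR profiles
#'
#' Emulates the serum-shock entrainment control: duplicate-replicate Ct
#' series for BMAL1 (period 24.15 h) and PER2 (period 20.40 h) over 0-48 h
#' at 4 h intervals, in antiphase (peak times half a period apart), with
#' GAPDH as the flat reference gene. In \code{"arrhythmic"} mode (the
#' clock-defective tumorigenic lines) the targets are noise around a flat
#' baseline.
#'
#' @param mode \code{"entrained"} or \code{"arrhythmic"}.
#' @param seed integer seed.
#' @param ct_noise_sd Gaussian noise SD on the Ct scale, in cycles
#'   (default 0.15).
#' @param log2_amplitude peak log2 fold-change amplitude of the entrained
#'   profiles (default 1.5).
#' @return A \code{\link{CtTable}} with features BMAL1, PER2 and GAPDH
#'   (reference), duplicate replicates, 13 timepoints.
#' @export
generateClockGeneProfiles <- function(mode = c("entrained", "arrhythmic"),
                                      seed = 1L, ct_noise_sd = 0.15,
                                      log2_amplitude = 1.5) {
  mode <- match.arg(mode)
  times <- seq(0, 48, by = 4)
  genes <- c(BMAL1 = 24.15, PER2 = 20.40)
  peak_h <- c(BMAL1 = 12, PER2 = 12 + 24.15 / 2)  # antiphase offset
  n_rep <- 2L
  base_ct <- c(BMAL1 = 26, PER2 = 27, GAPDH = 18)

  .withSeed(seed, {
    rows <- list()
    for (g in c(names(genes), "GAPDH")) {
      if (g == "GAPDH" || mode == "arrhythmic") {
        l2fc <- rep(0, length(times))
      } else {
        omega <- 2 * pi / genes[[g]]
        phi <- -omega * peak_h[[g]]
        # anchored so the log2 fold change is 0 at t = 0
        l2fc <- log2_amplitude * (cos(omega * times + phi) - cos(phi))
      }
      for (rep_i in seq_len(n_rep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = g,
          replicate_id = sprintf("rep%d", rep_i),
          time_h = times,
          ct = base_ct[[g]] - l2fc +
            stats::rnorm(length(times), 0, ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    CtTable(do.call(rbind, rows), reference = "GAPDH", baseline_time = 0)
  })
}

#' Simulate a replicated qPCR Ct dataset from ground-truth parameters
#'
#' Encodes each feature's cosine fold-change series into Ct values through
#' the inverse delta-delta-Ct model (target Ct = base Ct - log2 fold, flat
#' reference), so \code{\link{deltaDeltaCt}} recovers the generator's fold
#' series exactly at zero noise. Rhythmic truth rows use their
#' \code{(beta_true, omega_true, phi_true)}; non-rhythmic rows encode a
#' constant fold of 1. The log10-scale cosine amplitude translates to log2
#' fold change via \code{log2(10)}.
#'
#' @param truth data.frame as returned in
#'   \code{\link{generateExpressionDataset}()$truth} (or a subset of rows).
#' @param n_replicates biological replicates (default 3; >= 1).
#' @param missing_tail number of trailing timepoints left unmeasured
#'   (default 0); must be < the number of timepoints.
#' @param times_h time grid in hours (default 0-48 by 4 h, 13 points).
#' @param ct_noise_sd Gaussian Ct noise SD in cycles (default 0.15).
#' @param reference_id id of the flat reference feature added to the table
#'   (default "miR-106a-5p").
#' @param seed integer seed.
#' @return A \code{\link{CtTable}}.
#' @export
generateQpcrDataset <- function(truth, n_replicates = 3L, missing_tail = 0L,
                                times_h = seq(0, 48, by = 4),
                                ct_noise_sd = 0.15,
                                reference_id = "miR-106a-5p", seed = 1L) {
  stopifnot(is.data.frame(truth), n_replicates >= 1L)
  if (missing_tail >= length(times_h)) {
    stop("'missing_tail' must be smaller than the number of timepoints")
  }
  if (missing_tail > 0) {
    times_obs <- times_h[seq_len(length(times_h) - missing_tail)]
  } else {
    times_obs <- times_h
  }
  base_ct_target <- 28
  base_ct_ref <- 20

  .withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      if (isTRUE(truth$is_rhythmic[i])) {
        om <- truth$omega_true[i]; ph <- truth$phi_true[i]
        l2fc <- truth$beta_true[i] * log2(10) *
          (cos(om * times_obs + ph) - cos(ph))
      } else {
        l2fc <- rep(0, length(times_obs))
      }
      for (rep_i in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = truth$feature_id[i],
          replicate_id = sprintf("rep%d", rep_i),
          time_h = times_obs,
          ct = base_ct_target - l2fc +
            stats::rnorm(length(times_obs), 0, ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    for (rep_i in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = reference_id,
        replicate_id = sprintf("rep%d", rep_i),
        time_h = times_obs,
        ct = base_ct_ref + stats::rnorm(length(times_obs), 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
    CtTable(do.call(rbind, rows), reference = reference_id,
            baseline_time = times_h[1])
  })
}
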