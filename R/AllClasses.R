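#' Expression time course container
#'
#' An \code{ExpressionTimeCourse} is a
#' \link[SummarizedExperiment]{SummarizedExperiment} holding one assay
#' (\code{"exprs"}) of features x timepoints, with the sampling times (hours)
#' in \code{colData(x)$time_h} and a logical \code{metadata(x)$log_scale}
#' flag recording whether values are on the log10 scale.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("ExpressionTimeCourse", contains = "SummarizedExperiment")

setValidity("ExpressionTimeCourse", function(object) {
  msg <- NULL
  if (!"exprs" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'exprs' is required")
  }
  tm <- SummarizedExperiment::colData(object)$time_h
  if (is.null(tm)) {
    msg <- c(msg, "colData column 'time_h' is required")
  } else {
    if (!is.numeric(tm) || anyNA(tm) || !all(is.finite(tm))) {
      msg <- c(msg, "'time_h' must be finite numeric")
    } else if (ncol(object) >= 2L && any(diff(tm) <= 0)) {
      msg <- c(msg, "'time_h' must be strictly increasing")
    }
  }
  ls <- S4Vectors::metadata(object)$log_scale
  if (!is.logical(ls) || length(ls) != 1L || is.na(ls)) {
    msg <- c(msg, "metadata flag 'log_scale' must be TRUE or FALSE")
  }
  if (is.null(rownames(object))) {
    msg <- c(msg, "feature identifiers (rownames) are required")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionTimeCourse
#'
#' @param values numeric matrix, features in rows, timepoints in columns.
#' @param times_h numeric vector of sampling times in hours, strictly
#'   increasing, one per column.
#' @param feature_ids character vector of row identifiers; defaults to the
#'   rownames of \code{values}.
#' @param log_scale logical flag; \code{TRUE} when \code{values} are log10
#'   intensities, \code{FALSE} for raw intensities.
#' @return An \code{ExpressionTimeCourse}.
#' @examples
#' m <- matrix(rnorm(20), nrow = 4,
#'             dimnames = list(paste0("f", 1:4), NULL))
#' etc <- ExpressionTimeCourse(m, times_h = seq(0, 16, by = 4))
#' timesH(etc)
#' @export
ExpressionTimeCourse <- function(values, times_h,
                                 feature_ids = rownames(values),
                                 log_scale = TRUE) {
  values <- as.matrix(values)
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("feature_%04d", seq_len(nrow(values)))
  }
  if (length(feature_ids) != nrow(values)) {
    stop("'feature_ids' length must match the number of rows")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicated feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (length(times_h) != ncol(values)) {
    stop("'times_h' length must match the number of columns")
  }
  rownames(values) <- feature_ids
  colnames(values) <- paste0("t", format(times_h, trim = TRUE))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(time_h = as.numeric(times_h)))
  S4Vectors::metadata(se)$log_scale <- isTRUE(log_scale)
  methods::new("ExpressionTimeCourse", se)
}

#' Per-feature cosine fit results
#'
#' Container for the bounded cosinor fits of one expression time course:
#' one row per feature with amplitude \code{beta} (log10 scale, in [0, 30]),
#' angular frequency \code{omega} (rad/h, in [0, pi]), acrophase \code{phi}
#' (rad, canonicalized to [-pi, pi)), cosine correlation \code{r} (Pearson
#' correlation between the fitted curve and the mean-centered data),
#' residual sum of squares \code{sse} and the subtracted \code{mean_level},
#' plus the matrix of fitted curves on the common time grid.
#'
#' @slot fits DataFrame of per-feature parameters.
#' @slot fitted numeric matrix of fitted curves (features x timepoints).
#' @slot times_h numeric vector, the common time grid in hours.
#' @export
setClass("CosineFitSet",
         representation(fits = "DataFrame",
                        fitted = "matrix",
                        times_h = "numeric"))

setValidity("CosineFitSet", function(object) {
  msg <- NULL
  need <- c("feature_id", "beta", "omega", "phi", "r", "sse", "mean_level")
  if (!all(need %in% colnames(object@fits))) {
    msg <- c(msg, paste("fits must have columns:", paste(need, collapse = ", ")))
  } else {
    f <- object@fits
    if (any(f$beta < 0 | f$beta > 30, na.rm = TRUE)) {
      msg <- c(msg, "beta out of [0, 30]")
    }
    if (any(f$omega < 0 | f$omega > pi, na.rm = TRUE)) {
      msg <- c(msg, "omega out of [0, pi]")
    }
    if (any(abs(f$r) > 1 + 1e-12, na.rm = TRUE)) {
      msg <- c(msg, "|r| must be <= 1")
    }
  }
  if (nrow(object@fitted) != nrow(object@fits)) {
    msg <- c(msg, "fitted rows must match fits rows")
  }
  if (ncol(object@fitted) != length(object@times_h)) {
    msg <- c(msg, "fitted columns must match times_h length")
  }
  if (is.null(msg)) TRUE else msg
})

#' Replicated qPCR Ct table
#'
#' Long-format container of raw qPCR cycle-threshold values: one row per
#' (feature, replicate, time) with the Ct in cycles, plus the reference
#' (normalizer) feature and the baseline time used by
#' \code{\link{deltaDeltaCt}}. Missing timepoints are simply absent rows.
#'
#' @slot data data.frame with columns feature_id, replicate_id, time_h, ct.
#' @slot reference character, id of the reference feature (e.g. GAPDH for
#'   mRNA assays, miR-106a-5p for miRNA assays).
#' @slot baseline_time numeric, the time (hours) all fold changes are
#'   expressed against.
#' @export
setClass("CtTable",
         representation(data = "data.frame",
                        reference = "character",
                        baseline_time = "numeric"))

setValidity("CtTable", function(object) {
  msg <- NULL
  d <- object@data
  need <- c("feature_id", "replicate_id", "time_h", "ct")
  if (!all(need %in% colnames(d))) {
    msg <- c(msg, paste("data must have columns:", paste(need, collapse = ", ")))
  } else {
    key <- paste(d$feature_id, d$replicate_id, d$time_h, sep = "\r")
    if (anyDuplicated(key)) {
      msg <- c(msg, "duplicated (feature, replicate, time) keys")
    }
    if (!is.numeric(d$ct) || !is.numeric(d$time_h)) {
      msg <- c(msg, "'ct' and 'time_h' must be numeric")
    }
  }
  if (length(object@reference) != 1L) {
    msg <- c(msg, "'reference' must be a single feature id")
  }
  if (length(object@baseline_time) != 1L || !is.finite(object@baseline_time)) {
    msg <- c(msg, "'baseline_time' must be a single finite number")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CtTable
#'
#' @param data data.frame with columns \code{feature_id}, \code{replicate_id},
#'   \code{time_h}, \code{ct}.
#' @param reference id of the reference (normalizer) feature.
#' @param baseline_time baseline time in hours (default 0).
#' @return A \code{CtTable}.
#' @export
CtTable <- function(data, reference, baseline_time = 0) {
  data <- as.data.frame(data)
  data$feature_id <- as.character(data$feature_id)
  data$replicate_id <- as.character(data$replicate_id)
  methods::new("CtTable", data = data, reference = as.character(reference),
               baseline_time = as.numeric(baseline_time))
}

#' Synthetic-dataset configuration
#'
#' Parameters of the synthetic expression generator
#' (\code{\link{generateExpressionDataset}}). Defaults emulate the assumed
#' structure of a 2006-feature miRNA array profiled at 8 timepoints spaced
#' 4 h apart, with a rhythmic subset following
#' \eqn{g = \beta \cos(\omega t + \phi)} around a per-feature baseline.
#'
#' @slot n_features number of distinct features (default 2006).
#' @slot n_timepoints number of timepoints (default 8; >= 4).
#' @slot dt_hours sampling interval in hours (default 4).
#' @slot rhythmic_fraction fraction of features given a cosine signal
#'   (default 0.075, emulating the ~7\% rhythmic calls typical of these
#'   screens).
#' @slot omega_center,omega_sd centre and spread (rad/h) of the truncated
#'   Gaussian angular-frequency draws; defaults 0.2618 (= 2*pi/24) and 0.01,
#'   keeping simulated rhythmic features inside the 0.22-0.29 rad/h band
#'   used for classification. Draws are truncated to [0, pi].
#' @slot beta_range amplitude range (log10 scale) for rhythmic features,
#'   a sub-interval of [0, 30]; default [0.05, 0.5].
#' @slot n_phase_groups number of equally spaced acrophase centres (default
#'   6, emulating six phase clusters).
#' @slot phase_jitter_sd SD (rad) of the jitter around each phase centre
#'   (default 0.1).
#' @slot baseline_mean,baseline_sd location and scale (log10 intensity) of
#'   the per-feature baseline background component.
#' @slot expressed_fraction,expressed_shift,expressed_sd right-skew of the
#'   baseline distribution: a fraction of features (default 0.3) sits
#'   \code{expressed_shift} log10 units above the background with a wider SD,
#'   emulating the expressed-vs-background bimodality of real miRNA arrays.
#'   Set \code{expressed_fraction = 0} for a plain Gaussian baseline.
#' @slot noise_sd SD (log10 intensity) of the i.i.d. Gaussian measurement
#'   noise added to every value (default 0.02).
#' @slot replicate_probes_per_feature replicate spots per feature (default 1;
#'   30 emulates arrays that print ~30 replicates per probe sequence).
#' @slot ar1_drift if TRUE, non-rhythmic features get a smooth AR(1) drift
#'   component instead of pure i.i.d. noise (patterned but non-cosine
#'   profiles); default FALSE.
#' @slot ar1_rho,ar1_sd AR(1) coefficient and innovation SD of the drift.
#' @slot seed integer seed; all generator randomness derives from it.
#' @export
setClass("SimConfig",
         representation(n_features = "integer",
                        n_timepoints = "integer",
                        dt_hours = "numeric",
                        rhythmic_fraction = "numeric",
                        omega_center = "numeric",
                        omega_sd = "numeric",
                        beta_range = "numeric",
                        n_phase_groups = "integer",
                        phase_jitter_sd = "numeric",
                        baseline_mean = "numeric",
                        baseline_sd = "numeric",
                        expressed_fraction = "numeric",
                        expressed_shift = "numeric",
                        expressed_sd = "numeric",
                        noise_sd = "numeric",
                        replicate_probes_per_feature = "integer",
                        ar1_drift = "logical",
                        ar1_rho = "numeric",
                        ar1_sd = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  msg <- NULL
  if (object@n_features < 1L) msg <- c(msg, bad("n_features", "must be >= 1"))
  if (object@n_timepoints < 4L) {
    msg <- c(msg, bad("n_timepoints", "must be >= 4"))
  }
  if (!is.finite(object@dt_hours) || object@dt_hours <= 0) {
    msg <- c(msg, bad("dt_hours", "must be > 0"))
  }
  if (object@rhythmic_fraction < 0 || object@rhythmic_fraction > 1) {
    msg <- c(msg, bad("rhythmic_fraction", "must be in [0, 1]"))
  }
  if (object@omega_center < 0 || object@omega_center > pi) {
    msg <- c(msg, bad("omega_center", "must be in [0, pi]"))
  }
  if (object@omega_sd < 0) msg <- c(msg, bad("omega_sd", "must be >= 0"))
  if (length(object@beta_range) != 2L || object@beta_range[1] > object@beta_range[2] ||
      object@beta_range[1] < 0 || object@beta_range[2] > 30) {
    msg <- c(msg, bad("beta_range", "must be an ascending interval within [0, 30]"))
  }
  if (object@n_phase_groups < 1L) {
    msg <- c(msg, bad("n_phase_groups", "must be >= 1"))
  }
  if (object@noise_sd < 0) msg <- c(msg, bad("noise_sd", "must be >= 0"))
  if (object@baseline_sd < 0) msg <- c(msg, bad("baseline_sd", "must be >= 0"))
  if (object@expressed_fraction < 0 || object@expressed_fraction > 1) {
    msg <- c(msg, bad("expressed_fraction", "must be in [0, 1]"))
  }
  if (object@replicate_probes_per_feature < 1L) {
    msg <- c(msg, bad("replicate_probes_per_feature", "must be >= 1"))
  }
  if (object@ar1_rho <= -1 || object@ar1_rho >= 1) {
    msg <- c(msg, bad("ar1_rho", "must be in (-1, 1)"))
  }
  if (object@ar1_sd < 0) msg <- c(msg, bad("ar1_sd", "must be >= 0"))
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SimConfig-class constructor with defaults; every argument is
#'   validated and errors name the offending field.
#' @param n_features,n_timepoints,dt_hours,rhythmic_fraction,omega_center
#'   see slots.
#' @param omega_sd,beta_range,n_phase_groups,phase_jitter_sd see slots.
#' @param baseline_mean,baseline_sd,expressed_fraction,expressed_shift see
#'   slots.
#' @param expressed_sd,noise_sd,replicate_probes_per_feature see slots.
#' @param ar1_drift,ar1_rho,ar1_sd,seed see slots.
#' @export
simConfig <- function(n_features = 2006L,
                      n_timepoints = 8L,
                      dt_hours = 4,
                      rhythmic_fraction = 0.075,
                      omega_center = 0.2618,
                      omega_sd = 0.01,
                      beta_range = c(0.05, 0.5),
                      n_phase_groups = 6L,
                      phase_jitter_sd = 0.1,
                      baseline_mean = 2.0,
                      baseline_sd = 0.15,
                      expressed_fraction = 0.3,
                      expressed_shift = 1.0,
                      expressed_sd = 0.8,
                      noise_sd = 0.02,
                      replicate_probes_per_feature = 1L,
                      ar1_drift = FALSE,
                      ar1_rho = 0.6,
                      ar1_sd = 0.05,
                      seed = 1L) {
  methods::new("SimConfig",
               n_features = as.integer(n_features),
               n_timepoints = as.integer(n_timepoints),
               dt_hours = as.numeric(dt_hours),
               rhythmic_fraction = as.numeric(rhythmic_fraction),
               omega_center = as.numeric(omega_center),
               omega_sd = as.numeric(omega_sd),
               beta_range = as.numeric(beta_range),
               n_phase_groups = as.integer(n_phase_groups),
               phase_jitter_sd = as.numeric(phase_jitter_sd),
               baseline_mean = as.numeric(baseline_mean),
               baseline_sd = as.numeric(baseline_sd),
               expressed_fraction = as.numeric(expressed_fraction),
               expressed_shift = as.numeric(expressed_shift),
               expressed_sd = as.numeric(expressed_sd),
               noise_sd = as.numeric(noise_sd),
               replicate_probes_per_feature = as.integer(replicate_probes_per_feature),
               ar1_drift = isTRUE(ar1_drift),
               ar1_rho = as.numeric(ar1_rho),
               ar1_sd = as.numeric(ar1_sd),
               seed = .checkSeed(seed))
}
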