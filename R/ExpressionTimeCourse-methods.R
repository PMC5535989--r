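#' @describeIn ExpressionTimeCourse-class sampling times in hours.
#' @param x an \code{ExpressionTimeCourse}.
#' @export
setMethod("timesH", "ExpressionTimeCourse", function(x) {
  as.numeric(SummarizedExperiment::colData(x)$time_h)
})

#' @describeIn CosineFitSet-class the common time grid of the fits.
#' @export
setMethod("timesH", "CosineFitSet", function(x) x@times_h)

#' @describeIn ExpressionTimeCourse-class the expression matrix
#'   (features x timepoints).
#' @export
setMethod("exprValues", "ExpressionTimeCourse", function(x) {
  SummarizedExperiment::assay(x, "exprs")
})

#' @describeIn ExpressionTimeCourse-class TRUE when values are log10 scale.
#' @export
setMethod("isLogScale", "ExpressionTimeCourse", function(x) {
  isTRUE(S4Vectors::metadata(x)$log_scale)
})

#' @describeIn ExpressionTimeCourse-class set the log-scale flag.
#' @param value logical scalar.
#' @export
setReplaceMethod("isLogScale", "ExpressionTimeCourse", function(x, value) {
  S4Vectors::metadata(x)$log_scale <- isTRUE(value)
  x
})

setMethod("show", "ExpressionTimeCourse", function(object) {
  tm <- timesH(object)
  cat(sprintf("ExpressionTimeCourse: %d features x %d timepoints (%s h), %s scale\n",
              nrow(object), ncol(object),
              paste(range(tm), collapse = "-"),
              if (isLogScale(object)) "log10" else "raw"))
  methods::callNextMethod()
})

# internal: rebuild an ExpressionTimeCourse around a replacement value matrix
.replaceValues <- function(x, values, log_scale = isLogScale(x)) {
  ExpressionTimeCourse(values, times_h = timesH(x),
                       feature_ids = rownames(values), log_scale = log_scale)
}

#' @describeIn CosineFitSet-class per-feature fit parameters as a data.frame
#'   (columns feature_id, beta, omega, phi, r, sse, mean_level).
#' @param x a \code{CosineFitSet}.
#' @export
setMethod("fitParams", "CosineFitSet", function(x) {
  as.data.frame(x@fits)
})

#' @describeIn CosineFitSet-class matrix of fitted cosine curves.
#' @export
setMethod("fittedCurves", "CosineFitSet", function(x) x@fitted)

setMethod("show", "CosineFitSet", function(object) {
  f <- object@fits
  cat(sprintf("CosineFitSet: %d features over %d timepoints\n",
              nrow(f), length(object@times_h)))
  if (nrow(f) > 0) {
    cat(sprintf("  r: median %.3f | omega: median %.3f rad/h | beta: median %.3g\n",
                stats::median(f$r, na.rm = TRUE),
                stats::median(f$omega, na.rm = TRUE),
                stats::median(f$beta, na.rm = TRUE)))
  }
  invisible(NULL)
})

setMethod("length", "CosineFitSet", function(x) nrow(x@fits))

#' @describeIn CtTable-class the long-format Ct data.frame.
#' @param x a \code{CtTable}.
#' @export
setMethod("ctData", "CtTable", function(x) x@data)

#' @describeIn CtTable-class id of the reference (normalizer) feature.
#' @export
setMethod("referenceFeature", "CtTable", function(x) x@reference)

#' @describeIn CtTable-class baseline time in hours.
#' @export
setMethod("baselineTime", "CtTable", function(x) x@baseline_time)

setMethod("show", "CtTable", function(object) {
  d <- object@data
  cat(sprintf("CtTable: %d rows | %d features x %d replicates x %d timepoints\n",
              nrow(d), length(unique(d$feature_id)),
              length(unique(d$replicate_id)), length(unique(d$time_h))))
  cat(sprintf("  reference: %s | baseline: t = %g h\n",
              object@reference, object@baseline_time))
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d features x %d timepoints (dt = %g h), %.1f%% rhythmic\n",
              object@n_features, object@n_timepoints, object@dt_hours,
              100 * object@rhythmic_fraction))
  cat(sprintf("  omega ~ N(%.4f, %.4f) rad/h | beta ~ U[%g, %g] | %d phase groups\n",
              object@omega_center, object@omega_sd,
              object@beta_range[1], object@beta_range[2],
              object@n_phase_groups))
  cat(sprintf("  noise sd %.3g | %d replicate probes/feature | seed %d\n",
              object@noise_sd, object@replicate_probes_per_feature,
              object@seed))
  invisible(NULL)
})
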