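#' @name rhythmiR-generics
#' @title Generics for rhythmiR containers
#' @param x an object.
#' @param value replacement value.
#' @keywords internal
NULL

#' @rdname rhythmiR-generics
#' @export
setGeneric("timesH", function(x) standardGeneric("timesH"))

#' @rdname rhythmiR-generics
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname rhythmiR-generics
#' @export
setGeneric("isLogScale", function(x) standardGeneric("isLogScale"))

#' @rdname rhythmiR-generics
#' @export
setGeneric("isLogScale<-", function(x, value) standardGeneric("isLogScale<-"))

#' @rdname rhythmiR-generics
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @rdname rhythmiR-generics
#' @export
setGeneric("fittedCurves", function(x) standardGeneric("fittedCurves"))

#' @rdname rhythmiR-generics
#' @export
setGeneric("ctData", function(x) standardGeneric("ctData"))

#' @rdname rhythmiR-generics
#' @export
setGeneric("referenceFeature", function(x) standardGeneric("referenceFeature"))

#' @rdname rhythmiR-generics
#' @export
setGeneric("baselineTime", function(x) standardGeneric("baselineTime"))

#' Quantile normalization between arrays
#'
#' Forces every column (array/timepoint) to share the identical multiset of
#' values: each value is replaced by the mean, across columns, of the values
#' at its within-column rank; ties receive the mean of the rank-mean values
#' they span. Missing values are rejected.
#'
#' @param x a numeric matrix or \code{\link{ExpressionTimeCourse}} of raw,
#'   background-corrected intensities with at least two columns.
#' @return An object of the same class with normalized values.
#' @seealso \code{\link{log10Transform}}, \code{\link{collapseProbes}} for
#'   the downstream preprocessing steps.
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' Log10 transform with a floor
#'
#' Replaces each value v by \code{log10(max(v, floor))}. For an
#' \code{ExpressionTimeCourse} the \code{log_scale} metadata flag must be
#' FALSE on input (transforming twice is an error) and is set TRUE on output.
#'
#' @param x numeric matrix or \code{\link{ExpressionTimeCourse}} on the raw
#'   intensity scale.
#' @param floor positive lower bound applied before taking logs (default 1).
#' @return transformed object of the same class.
#' @export
setGeneric("log10Transform", function(x, floor = 1) standardGeneric("log10Transform"))

#' Collapse replicate probe spots
#'
#' Aggregates matrix rows that measure the same (miRNA, probe) pair, taking
#' the per-timepoint median (default) across replicate spots. Distinct probe
#' sequences of one miRNA (probe_index) are kept as separate output rows.
#'
#' @param x numeric matrix or \code{\link{ExpressionTimeCourse}} whose rows
#'   are probe spots.
#' @param probe_map data.frame with columns \code{probe_id},
#'   \code{mirna_id}, \code{probe_index}; every row of \code{x} must be
#'   listed.
#' @param method aggregation function name, \code{"median"} (default) or
#'   \code{"mean"}.
#' @return collapsed object of the same class, one row per
#'   (mirna_id, probe_index); output ids are \code{mirna_id} when a miRNA
#'   has one probe, else \code{mirna_id_p<index>}.
#' @export
setGeneric("collapseProbes", function(x, probe_map, method = "median")
  standardGeneric("collapseProbes"))

#' Matrix randomization schemes for null data
#'
#' Builds structure-free null data from an expression matrix by one of five
#' shuffling schemes: \describe{
#'   \item{TL}{time-label: one random permutation of the column order applied
#'     to all rows;}
#'   \item{RW}{row-wise: values permuted independently within each row;}
#'   \item{CW}{column-wise: values permuted independently within each column;}
#'   \item{RCW}{row-column-wise: RW then CW, sequentially;}
#'   \item{RCWB}{row-column-wise by blocks: columns split into
#'     \code{n_blocks} contiguous blocks and RW-then-CW applied independently
#'     within each block.}
#' }
#' Every scheme conserves the global multiset of matrix values; results are
#' reproducible for a given seed.
#'
#' @param x numeric matrix or \code{\link{ExpressionTimeCourse}}.
#' @param kind one of "TL", "RW", "CW", "RCW", "RCWB".
#' @param seed integer seed.
#' @param n_blocks number of contiguous column blocks for RCWB (default 2;
#'   must be >= 2 and <= the column count).
#' @return randomized object of the same class.
#' @export
setGeneric("randomizeMatrix", function(x, kind, seed, n_blocks = 2L)
  standardGeneric("randomizeMatrix"))
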