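.quantileNormalizeMatrix <- function(m) {
  .assertFiniteMatrix(m, "input to quantileNormalize")
  if (ncol(m) < 2L) {
    stop("quantile normalization needs at least 2 columns")
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
  .quantileNormalizeMatrix(x)
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "ExpressionTimeCourse", function(x) {
  .replaceValues(x, .quantileNormalizeMatrix(exprValues(x)))
})

.log10Matrix <- function(m, floor) {
  .assertFiniteMatrix(m, "input to log10Transform")
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stop("'floor' must be a single positive number")
  }
  log10(pmax(m, floor))
}

#' @rdname log10Transform
#' @export
setMethod("log10Transform", "matrix", function(x, floor = 1) {
  .log10Matrix(x, floor)
})

#' @rdname log10Transform
#' @export
setMethod("log10Transform", "ExpressionTimeCourse", function(x, floor = 1) {
  if (isLogScale(x)) {
    stop("matrix is already log10-transformed (log_scale flag is TRUE)")
  }
  .replaceValues(x, .log10Matrix(exprValues(x), floor), log_scale = TRUE)
})

.collapseMatrix <- function(m, probe_map, method) {
  .assertFiniteMatrix(m, "input to collapseProbes")
  method <- match.arg(method, c("median", "mean"))
  need <- c("probe_id", "mirna_id", "probe_index")
  if (!is.data.frame(probe_map) || !all(need %in% colnames(probe_map))) {
    stop("'probe_map' must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(probe_map$probe_id)) {
    stop("'probe_map' maps some probe_id more than once")
  }
  unmapped <- setdiff(rownames(m), probe_map$probe_id)
  if (length(unmapped) > 0) {
    stop("unmapped probes: ", paste(utils::head(unmapped, 10), collapse = ", "),
         if (length(unmapped) > 10) sprintf(" ... (%d total)", length(unmapped)))
  }
  map <- probe_map[match(rownames(m), probe_map$probe_id), ]
  key <- paste(map$mirna_id, map$probe_index, sep = "\r")
  keys <- unique(key)                      # first-appearance order
  agg <- if (method == "median") stats::median else mean
  out <- matrix(NA_real_, length(keys), ncol(m),
                dimnames = list(NULL, colnames(m)))
  for (i in seq_along(keys)) {
    rows <- m[key == keys[i], , drop = FALSE]
    out[i, ] <- apply(rows, 2, agg)
  }
  first <- match(keys, key)
  mirna <- map$mirna_id[first]
  pidx <- map$probe_index[first]
  multi <- mirna %in% mirna[duplicated(mirna)]
  rownames(out) <- ifelse(multi, sprintf("%s_p%d", mirna, pidx), mirna)
  attr(out, "mirna_id") <- mirna
  attr(out, "probe_index") <- pidx
  out
}

#' @rdname collapseProbes
#' @export
setMethod("collapseProbes", "matrix", function(x, probe_map, method = "median") {
  .collapseMatrix(x, probe_map, method)
})

#' @rdname collapseProbes
#' @export
setMethod("collapseProbes", "ExpressionTimeCourse",
          function(x, probe_map, method = "median") {
  m <- .collapseMatrix(exprValues(x), probe_map, method)
  out <- .replaceValues(x, m)
  SummarizedExperiment::rowData(out)$mirna_id <- attr(m, "mirna_id")
  SummarizedExperiment::rowData(out)$probe_index <- attr(m, "probe_index")
  out
})
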