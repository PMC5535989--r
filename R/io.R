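#' Read and write expression matrices as TSV
#'
#' The on-disk format is one header row \code{feature_id<TAB>t0<TAB>t4...}
#' (times encoded as \code{t<hours>}) followed by one row per feature.
#' Values are written at full double precision so write-then-read round
#' trips are lossless. Non-uniform time grids are accepted.
#'
#' @param path file path.
#' @param log_scale logical flag stored on the returned object (the TSV
#'   itself does not record scale); default TRUE.
#' @return \code{readExpressionTSV} returns an
#'   \code{\link{ExpressionTimeCourse}}; \code{writeExpressionTSV} returns
#'   \code{path} invisibly.
#' @export
readExpressionTSV <- function(path, log_scale = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 1L || !nzchar(lines[1])) {
    stop("parse error at line 1: empty file or empty header: ", path)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "feature_id" ||
      !all(grepl("^t", header[-1]))) {
    stop("parse error at line 1: malformed header, expected ",
         "'feature_id\\tt<hours>...'")
  }
  times <- suppressWarnings(as.numeric(sub("^t", "", header[-1])))
  if (anyNA(times)) {
    stop("parse error at line 1: non-numeric time in header")
  }
  if (length(lines) < 2L) stop("parse error: no data rows in ", path)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    stop("parse error at line ", which(nfield != length(header))[1] + 1L,
         ": wrong number of fields")
  }
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    line <- which(duplicated(ids))[1] + 1L
    stop("parse error at line ", line, ": duplicated feature_id '",
         ids[duplicated(ids)][1], "'")
  }
  values <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(body, `[`, -1L))),
           nrow = length(body), byrow = TRUE))
  if (anyNA(values)) {
    bad <- which(rowSums(is.na(values)) > 0)[1] + 1L
    stop("parse error at line ", bad, ": non-numeric cell")
  }
  ExpressionTimeCourse(values, times_h = times, feature_ids = ids,
                       log_scale = log_scale)
}

#' @rdname readExpressionTSV
#' @param x an \code{ExpressionTimeCourse}.
#' @export
writeExpressionTSV <- function(x, path) {
  stopifnot(methods::is(x, "ExpressionTimeCourse"))
  m <- exprValues(x)
  header <- paste(c("feature_id",
                    paste0("t", format(timesH(x), trim = TRUE, digits = 15))),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write long-format Ct tables as TSV
#'
#' Columns: feature_id, replicate_id, time_h, ct. The reference feature and
#' baseline time are stored in a \code{# reference=} / \code{# baseline=}
#' comment header so the round trip is complete.
#'
#' @param path file path.
#' @return \code{readCtTSV} returns a \code{\link{CtTable}};
#'   \code{writeCtTSV} returns \code{path} invisibly.
#' @export
readCtTSV <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  ref <- sub("^# reference=", "", grep("^# reference=", meta, value = TRUE))
  base <- as.numeric(sub("^# baseline=", "",
                         grep("^# baseline=", meta, value = TRUE)))
  if (length(ref) != 1L || length(base) != 1L || is.na(base)) {
    stop("parse error: missing '# reference=' or '# baseline=' header in ",
         path)
  }
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("feature_id", "replicate_id", "time_h", "ct")
  if (!all(need %in% colnames(d))) {
    stop("parse error: Ct TSV must have columns ", paste(need, collapse = ", "))
  }
  CtTable(d, reference = ref, baseline_time = base)
}

#' @rdname readCtTSV
#' @param x a \code{CtTable}.
#' @export
writeCtTSV <- function(x, path) {
  stopifnot(methods::is(x, "CtTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# reference=%s", referenceFeature(x)),
               sprintf("# baseline=%.17g", baselineTime(x))), con)
  utils::write.table(ctData(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
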