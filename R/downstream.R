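#' Ward clustering of rhythmic features by peak phase
#'
#' Phase is circular, so each rhythmic feature's peak phase angle
#' \eqn{\theta = 2\pi \cdot peak\_phase\_h / period\_h} is embedded on the
#' unit circle as (cos theta, sin theta) and clustered by Ward agglomeration
#' (\code{hclust} method \code{"ward.D2"}) on Euclidean distances, cutting
#' the tree at \code{k} clusters. The assignment is deterministic given the
#' input order.
#'
#' @param calls data.frame from \code{\link{classifyRhythmic}}; only rows
#'   with \code{is_rhythmic} are clustered.
#' @param k number of clusters (default 6).
#' @return data.frame with feature_id, cluster (1..k), theta (rad) for every
#'   rhythmic feature.
#' @export
clusterByPhase <- function(calls, k = 6L) {
  stopifnot(is.data.frame(calls), k >= 1L)
  rc <- calls[calls$is_rhythmic, , drop = FALSE]
  if (nrow(rc) < k) {
    stop("fewer rhythmic features (", nrow(rc), ") than clusters (", k, ")")
  }
  theta <- 2 * pi * rc$peak_phase_h / rc$period_h
  emb <- cbind(cos(theta), sin(theta))
  hc <- stats::hclust(stats::dist(emb), method = "ward.D2")
  data.frame(feature_id = rc$feature_id,
             cluster = stats::cutree(hc, k = k),
             theta = theta,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation of a set overlap
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two feature sets drawn from a common universe:
#' \eqn{p = \sum_{i \ge k} C(|A|, i) C(N - |A|, |B| - i) / C(N, |B|)}.
#'
#' @param setA,setB character vectors of feature identifiers.
#' @param universe_size N, the number of assayed features both sets were
#'   drawn from.
#' @return list with sizes |A|, |B|, N, the overlap k and \code{p_value}.
#' @examples
#' overlapSignificance(letters[1:4], letters[2:6], universe_size = 10)
#' @export
overlapSignificance <- function(setA, setB, universe_size) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  N <- as.integer(universe_size)
  if (length(setA) > N || length(setB) > N) {
    stop("set sizes cannot exceed the universe size")
  }
  k <- length(intersect(setA, setB))
  p <- stats::phyper(k - 1L, length(setA), N - length(setA), length(setB),
                     lower.tail = FALSE)
  list(size_a = length(setA), size_b = length(setB), universe = N,
       overlap = k, p_value = p)
}

#' Venn region counts for two or three feature sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return data.frame of disjoint Venn regions (membership pattern and
#'   count); the regions partition the union of the sets.
#' @export
vennCounts <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L))
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, function(s) unique(as.character(s)))
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(all_ids, names(sets)))
  pattern <- apply(member, 1L, function(m) paste(ifelse(m, "1", "0"),
                                                 collapse = ""))
  pats <- apply(expand.grid(rep(list(c("1", "0")), length(sets))), 1L,
                paste, collapse = "")
  pats <- setdiff(pats, paste(rep("0", length(sets)), collapse = ""))
  data.frame(region = pats,
             count = vapply(pats, function(p) sum(pattern == p), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

.formatPercent <- function(count, universe, display = c("truncate", "round")) {
  display <- match.arg(display)
  pct <- 100 * count / universe
  if (display == "truncate") floor(pct * 100) / 100 else round(pct, 2)
}

#' Summarize rhythmicity calls across datasets
#'
#' Per-dataset rhythmic counts and percentage of the assayed universe
#' (two-decimal display, truncated by default to match conventional printed
#' percentages; rounding is available), optional per-cluster counts, and
#' pairwise/triple overlap statistics with Venn region counts when 2-3
#' datasets are given.
#'
#' @param calls_list named list of call data.frames from
#'   \code{\link{classifyRhythmic}} (one per dataset / cell line).
#' @param universe_size number of assayed features (defaults to the number
#'   of rows of the first call table).
#' @param clustering optional \code{\link{clusterByPhase}} result for the
#'   first dataset, adding per-cluster counts.
#' @param display percentage display convention, \code{"truncate"}
#'   (default) or \code{"round"}.
#' @return list with \code{summary} (data.frame: dataset, n_rhythmic,
#'   pct_rhythmic), optional \code{cluster_counts}, and for 2-3 datasets
#'   \code{overlaps} (pairwise hypergeometric tests) and \code{venn}.
#' @export
summarizeCalls <- function(calls_list, universe_size = NULL,
                           clustering = NULL,
                           display = c("truncate", "round")) {
  display <- match.arg(display)
  if (is.data.frame(calls_list)) calls_list <- list(dataset1 = calls_list)
  if (is.null(names(calls_list))) {
    names(calls_list) <- sprintf("dataset%d", seq_along(calls_list))
  }
  if (is.null(universe_size)) universe_size <- nrow(calls_list[[1L]])
  rhythmic_sets <- lapply(calls_list,
                          function(d) d$feature_id[d$is_rhythmic])
  summary <- data.frame(
    dataset = names(calls_list),
    n_rhythmic = vapply(rhythmic_sets, length, 0L),
    pct_rhythmic = vapply(rhythmic_sets, function(s)
      .formatPercent(length(s), universe_size, display), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(summary = summary, universe = universe_size)
  if (!is.null(clustering)) {
    out$cluster_counts <- as.data.frame(table(cluster = clustering$cluster),
                                        stringsAsFactors = FALSE)
  }
  if (length(calls_list) %in% c(2L, 3L)) {
    pairs <- utils::combn(names(calls_list), 2L, simplify = FALSE)
    out$overlaps <- do.call(rbind, lapply(pairs, function(pr) {
      ov <- overlapSignificance(rhythmic_sets[[pr[1]]],
                                rhythmic_sets[[pr[2]]], universe_size)
      data.frame(set_a = pr[1], set_b = pr[2], size_a = ov$size_a,
                 size_b = ov$size_b, overlap = ov$overlap,
                 p_value = ov$p_value, stringsAsFactors = FALSE)
    }))
    out$venn <- vennCounts(rhythmic_sets)
  }
  out
}

#' Z-scale rhythmic features for heatmap display
#'
#' Per-feature z-scores over the time axis ((x - mean) / sd), rows restricted
#' to rhythmic features and ordered by phase cluster then peak phase, ready
#' for heatmap export. Zero-variance rows become all zeros with a warning.
#'
#' @param x \code{\link{ExpressionTimeCourse}} or numeric matrix.
#' @param calls data.frame from \code{\link{classifyRhythmic}}.
#' @param clustering data.frame from \code{\link{clusterByPhase}}; optional
#'   (rows then ordered by peak phase only).
#' @return numeric matrix of z-scores with ordered rhythmic features as rows.
#' @export
zscaleForHeatmap <- function(x, calls, clustering = NULL) {
  m <- if (methods::is(x, "ExpressionTimeCourse")) exprValues(x) else
    as.matrix(x)
  rc <- calls[calls$is_rhythmic, , drop = FALSE]
  if (nrow(rc) == 0L) stop("no rhythmic features to display")
  missing_rows <- setdiff(rc$feature_id, rownames(m))
  if (length(missing_rows) > 0) {
    stop("calls refer to features absent from the matrix: ",
         paste(utils::head(missing_rows, 5), collapse = ", "))
  }
  ord <- order(rc$peak_phase_h)
  if (!is.null(clustering)) {
    cl <- clustering$cluster[match(rc$feature_id, clustering$feature_id)]
    ord <- order(cl, rc$peak_phase_h)
  }
  rc <- rc[ord, , drop = FALSE]
  sub <- m[rc$feature_id, , drop = FALSE]
  mu <- rowMeans(sub)
  sd_ <- apply(sub, 1L, stats::sd)
  flat <- sd_ == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance feature(s) set to all-zero rows")
    sd_[flat] <- 1
  }
  z <- (sub - mu) / sd_
  z[flat, ] <- 0
  z
}
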