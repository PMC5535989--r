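#' Adjusted Rand index between two partitions
#'
#' Agreement between two clusterings of the same items, corrected for
#' chance: 1 for identical partitions (up to relabeling), ~0 for independent
#' ones. Used to score recovery of generator phase groups by
#' \code{\link{clusterByPhase}}.
#'
#' @param a,b integer/factor vectors of equal length; NA pairs are dropped.
#' @return numeric scalar in [-1, 1].
#' @export
adjustedRand <- function(a, b) {
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
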