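.canonicalPhase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

.checkSeed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != as.integer(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  withr::with_seed(.checkSeed(seed), expr)
}

.assertFiniteMatrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (anyNA(m) || !all(is.finite(m))) {
    stop(sprintf("%s contains missing or non-finite values", what),
         call. = FALSE)
  }
  invisible(m)
}
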