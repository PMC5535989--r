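# Independent oracles the implementation is checked against.

# Exhaustive (omega, phi) grid search for the bounded cosine fit: amplitude
# solved in closed form per node against the constant-projected basis (the
# same objective the fitter minimizes). Deliberately brute force.
oracle_cosine_sse <- function(y, times, omega_step = 0.005, phi_step = 0.02) {
  yc <- y - mean(y)
  best <- sum(yc^2)                       # beta = 0 fallback
  phis <- seq(-pi, pi - phi_step, by = phi_step)
  for (w in seq(omega_step, pi, by = omega_step)) {
    C <- cos(outer(w * times, phis, "+"))           # T x P
    Cc <- C - rep(colMeans(C), each = length(times))
    den <- colSums(Cc^2)
    num <- as.numeric(crossprod(Cc, yc))
    beta <- ifelse(den > 0, pmin(30, pmax(0, num / den)), 0)
    sse <- sum(yc^2) - 2 * beta * num + beta^2 * den
    best <- min(best, sse)
  }
  best
}

# Same exhaustive grid oracle, batched over the rows of Y for speed.
oracle_cosine_sse_matrix <- function(Y, times, omega_step = 0.005,
                                     phi_step = 0.02) {
  Yc <- Y - rowMeans(Y)
  yy <- rowSums(Yc^2)
  best <- yy                               # beta = 0 fallback
  phis <- seq(-pi, pi - phi_step, by = phi_step)
  for (w in seq(omega_step, pi, by = omega_step)) {
    C <- cos(outer(w * times, phis, "+"))            # T x P
    Cc <- C - rep(colMeans(C), each = length(times))
    den <- colSums(Cc^2)                             # P
    num <- crossprod(Cc, t(Yc))                      # P x n
    beta <- num / ifelse(den > 0, den, 1)
    beta[beta < 0] <- 0; beta[beta > 30] <- 30
    beta[den == 0, ] <- 0
    sse <- rep(yy, each = length(phis)) - 2 * beta * num + beta^2 * den
    best <- pmin(best, apply(sse, 2L, min))
  }
  best
}

# Exhaustive hypergeometric tail: enumerate every possible draw of |B| ids
# from a universe of size N and count draws overlapping a fixed set A in at
# least k elements. Exact for small N.
oracle_hyper_p <- function(N, size_a, size_b, k) {
  A <- seq_len(size_a)
  draws <- utils::combn(N, size_b)
  hits <- apply(draws, 2L, function(d) sum(d %in% A) >= k)
  mean(hits)
}

# small CosineFitSet builder for threshold-logic tests
make_fitset <- function(beta, omega, phi = rep(0, length(beta)),
                        r = rep(1, length(beta))) {
  n <- length(beta)
  fits <- S4Vectors::DataFrame(
    feature_id = sprintf("f%02d", seq_len(n)),
    beta = beta, omega = omega, phi = phi, r = r,
    sse = rep(0, n), mean_level = rep(0, n))
  methods::new("CosineFitSet", fits = fits,
               fitted = matrix(0, n, 8), times_h = seq(0, 28, by = 4))
}

expect_same_multiset <- function(a, b) {
  expect_identical(sort(as.numeric(a)), sort(as.numeric(b)))
}
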