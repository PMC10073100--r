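# Independent brute-force oracles used to cross-check the package's
# implementations on tiny instances. These deliberately use naive loops and
# base R only, never the code paths they test.

# neighbour ranks of every point from a distance matrix, ties by index
brute_ranks <- function(D, i) {
  others <- setdiff(seq_len(nrow(D)), i)
  d <- D[i, others]
  r <- integer(length(others))
  ord <- others[order(d, others)]
  match(others, ord)
}

# co-ranking matrix by direct enumeration
brute_coranking <- function(D_high, D_low) {
  n <- nrow(D_high)
  C <- matrix(0L, n - 1L, n - 1L)
  for (i in seq_len(n)) {
    rh <- brute_ranks(D_high, i)
    rl <- brute_ranks(D_low, i)
    for (t in seq_along(rh)) C[rh[t], rl[t]] <- C[rh[t], rl[t]] + 1L
  }
  C
}

# Q_NX curve, split point and Q_local/Q_global by direct summation
brute_quality <- function(D_high, D_low) {
  n <- nrow(D_high)
  C <- brute_coranking(D_high, D_low)
  q <- numeric(n - 1L)
  for (K in seq_len(n - 1L)) {
    q[K] <- sum(C[seq_len(K), seq_len(K)]) / (K * n)
  }
  split_K <- which.max(q - seq_len(n - 1L) / (n - 1L))
  list(Q_NX = q, split_K = split_K,
       Q_local = mean(q[seq_len(n - 1L) <= split_K]),
       Q_global = mean(q[seq_len(n - 1L) > split_K]))
}

# plain 1-NN classifier by exhaustive search
brute_1nn <- function(Ztr, ltr, Zte) {
  apply(Zte, 1, function(z) {
    d <- sqrt(colSums((t(Ztr) - z)^2))
    ltr[which.min(d)]
  })
}

# random point strictly inside the Poincare ball of curvature -K
rand_ball <- function(d, K = 1, rmax = 0.95) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2)) * stats::runif(1, 0, rmax / sqrt(K))
}

# random point on the hyperboloid via the exponential map formulas written
# out directly (independent of the package's exp_map)
rand_hyperboloid <- function(d, K = 1, scale = 1.5) {
  v <- stats::rnorm(d) * scale
  r <- sqrt(sum(v^2))
  c(cosh(r / sqrt(K)), sqrt(K) * sinh(r / sqrt(K)) * v / r)
}
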