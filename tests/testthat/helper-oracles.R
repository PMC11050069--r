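# Independent oracles kept deliberately naive: they re-derive the expected
# values by enumeration or first-principles formulas, never by calling the
# code paths they check.

# Benjamini-Hochberg step-up by the definition: sort p ascending, q_(i) =
# min_{j >= i} p_(j) * m / j, capped at 1, returned in the input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail P(X >= k) as an explicit sum of binomial
# coefficients (exact in doubles for N <= 25).
hyper_tail_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (k <= max(0, n - (N - K))) return(1)
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Brute-force tail by enumerating every size-n subset of 1:N, with 1:K as
# the marked class.
hyper_tail_enumeration <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Ordinary pooled two-sample t for one gene.
pooled_t_oracle <- function(x_poly, x_dip) {
  n1 <- length(x_poly); n2 <- length(x_dip)
  lfc <- mean(x_poly) - mean(x_dip)
  s2 <- (sum((x_poly - mean(x_poly))^2) + sum((x_dip - mean(x_dip))^2)) /
    (n1 + n2 - 2)
  t <- lfc / sqrt(s2 * (1 / n1 + 1 / n2))
  list(lfc = lfc, t = t,
       p = 2 * stats::pt(-abs(t), df = n1 + n2 - 2))
}

# Consensus by explicit double loop over genes and cohorts.
consensus_oracle <- function(direction_matrix) {
  up <- character(); down <- character()
  for (g in rownames(direction_matrix)) {
    calls <- direction_matrix[g, ]
    if (all(calls == "up")) up <- c(up, g)
    if (all(calls == "down")) down <- c(down, g)
  }
  list(up = up, down = down)
}

# Exact null expectation of P(p < alpha) for a hypergeometric upper-tail
# test with parameters (N, K, n): the tail mass above the smallest k whose
# tail falls below alpha. Discrete tests are super-uniform, so this is the
# correct calibration reference (it is <= alpha).
expected_fraction_below <- function(alpha, N, K, n) {
  kk <- 0:min(K, n)
  tails <- stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
  hit <- kk[tails < alpha]
  if (length(hit) == 0) return(0)
  stats::phyper(min(hit) - 1, K, N - K, n, lower.tail = FALSE)
}
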