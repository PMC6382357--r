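# Independent brute-force oracles used to pin expected values.
# These enumerate the full combinatorial space and never share code with
# the implementations they check.

# distribution of max|RS| over all C(N, k) member placements
oracle_rs_max_values <- function(N, k) {
  combos <- utils::combn(N, k)
  apply(combos, 2L, function(pos) {
    incr <- rep(-k, N)
    incr[pos] <- N - k
    max(abs(cumsum(incr)))
  })
}

# P(max|RS| >= s) by enumeration
oracle_running_sum_p <- function(N, k, s) {
  if (s <= 0) return(1)
  mean(oracle_rs_max_values(N, k) >= s)
}

# upper-tail hypergeometric by enumerating all draws of size n from a
# universe 1..N whose category is 1..K
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- apply(draws, 2L, function(d) sum(d <= K))
  mean(overlap >= k)
}

# exact two-sided Mann-Whitney p by enumerating all labelings
oracle_mw_two_sided <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n, n1)
  pooled_ranks <- rank(c(a, b))
  u_all <- apply(labelings, 2L, function(idx)
    sum(pooled_ranks[idx]) - n1 * (n1 + 1) / 2)
  u_star <- min(u_obs, n1 * n2 - u_obs)
  min(1, 2 * mean(u_all <= u_star))
}
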