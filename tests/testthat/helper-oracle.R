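# Independent exact-rational oracle for the sequential hypergeometric
# region score: literal transcription of the statistic's definition, with
# upper-tail probabilities computed as explicit sums of binomial-coefficient
# ratios (exact in double precision for the small N used in tests). Shares
# no code path with score_region().

oracle_hyper_upper <- function(k, K, N, n) {
  # P(X >= k) for X ~ Hypergeometric(N population, K successes, n draws)
  j <- seq(max(k, max(0, n - (N - K))), min(n, K))
  if (length(j) == 0L || min(j) > min(n, K)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

oracle_score_region <- function(member_ranks, N_total) {
  r <- sort(member_ranks)            # distinct ranks assumed
  stopifnot(!anyDuplicated(r))
  r <- r[-1]                         # exclude the most significant member
  m <- length(r)
  if (m == 0L) return(1)
  K <- rev(r)                        # least -> most significant
  p <- 1
  for (i in seq_len(m)) {
    k_i <- sum(r <= K[i])
    n_i <- if (i == 1L) m else sum(r <= K[i - 1L]) - 1L
    N_i <- if (i == 1L) N_total else K[i - 1L] - 1L
    p <- p * oracle_hyper_upper(k_i, K[i], N_i, n_i)
  }
  p
}
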