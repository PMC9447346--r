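#' Sequential hypergeometric region score
#'
#' Scores a set of CpG significance ranks drawn from a track of `N_total`
#' probes. The most significant member (smallest rank; ties broken by the
#' earliest position, i.e. input order) is excluded as the conditioning draw;
#' the remaining m members, ordered from least to most significant, each
#' contribute an upper-tail hypergeometric probability whose population,
#' success and draw counts shrink as the previous member's rank is
#' conditioned away:
#' \deqn{p_{region} = \prod_{i=1}^{m} P(X \ge k_i),\quad
#'       X \sim \mathrm{Hyper}(N_i, K_i, n_i)}
#' with \eqn{K_i} the i-th member's rank, \eqn{k_i} the number of members
#' ranked at least as significant, \eqn{n_1 = m}, \eqn{n_i = k_{i-1}-1},
#' \eqn{N_1 = N_{total}}, \eqn{N_i = K_{i-1}-1}. A single-member region gives
#' the empty product, 1. Tied ranks within the region (which share the
#' maximal count under the track's tie rule) are expanded to the distinct
#' rank positions they occupy, earliest position most significant, so the
#' sequence is always well defined.
#'
#' All accumulation is in log space; the returned linear-scale value is
#' floored at the smallest positive double so it never underflows to zero.
#' Use `log10 = TRUE` to obtain the exact magnitude.
#'
#' @param member_ranks integer ranks of the region's member CpGs, in position
#'   order along the chromosome.
#' @param N_total number of probes in the significance track.
#' @param log10 return log10(p) instead of p.
#' @return the region score, a probability in (0, 1] (or its log10).
#' @export
score_region <- function(member_ranks, N_total, log10 = FALSE) {
  l10 <- score_region_log10(member_ranks, N_total)
  if (log10) l10 else max(10^l10, .Machine$double.xmin)
}

score_region_log10 <- function(member_ranks, N_total) {
  r <- as.numeric(member_ranks)
  if (length(r) == 0L) stop("region has no member CpGs")
  if (anyNA(r) || any(r < 1) || any(r > N_total) || any(r != floor(r))) {
    stop("member ranks must be integers in [1, N_total]")
  }
  eff <- detie_ranks(r)
  if (eff[1] < 1) stop("inconsistent member ranks (tied ranks overlap rank 1)")
  m <- length(eff) - 1L
  if (m == 0L) return(0)
  K <- eff[(m + 1L):2L]                 # descending: least -> most significant
  n <- m:1                              # with distinct ranks, k_i = n_i
  Npop <- c(N_total, K[-length(K)] - 1)
  if (any(Npop <= 0) || any(n <= 0)) stop("inconsistent ranks: population exhausted")
  lf <- stats::phyper(n - 1, K, Npop - K, n, lower.tail = FALSE, log.p = TRUE)
  sum(lf) / log(10)
}

# Expand tied max-count ranks into the distinct rank positions they occupy:
# a group of t members sharing rank K becomes K-t+1, ..., K, with the
# earliest input position taken as most significant. Returns the effective
# ranks sorted ascending. Errors (via caller) if groups collide.
detie_ranks <- function(r) {
  o <- order(r, seq_along(r))
  rs <- r[o]
  runs <- rle(rs)
  eff <- unlist(lapply(seq_along(runs$values), function(i) {
    v <- runs$values[i]; t <- runs$lengths[i]
    seq(v - t + 1, v)
  }), use.names = FALSE)
  if (any(diff(eff) <= 0)) stop("inconsistent member ranks (tied groups collide)")
  eff
}
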