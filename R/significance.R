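# Per-CpG two-group testing and the significance track feeding the window
# score: p-values, delta-beta, and max-count significance ranks.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

group_indices <- function(beta, groups) {
  if (!all(groups$sample_id %in% colnames(beta))) {
    stop("sample sheet contains samples absent from beta matrix")
  }
  lev <- unique(groups$group)
  if (length(lev) != 2L) stop("exactly two groups required, got ", length(lev))
  idx1 <- match(groups$sample_id[groups$group == lev[1]], colnames(beta))
  idx2 <- match(groups$sample_id[groups$group == lev[2]], colnames(beta))
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("each group needs >= 2 samples")
  }
  list(idx1 = idx1, idx2 = idx2, levels = lev)
}

# Row-wise rank matrix plus tie bookkeeping reused across permutations.
row_rank_info <- function(x) {
  R <- t(apply(x, 1L, rank))
  tie3 <- apply(x, 1L, function(v) {
    t <- table(v); sum(t^3 - t)
  })
  list(R = R, tie3 = as.numeric(tie3), has_ties = tie3 > 0)
}

# Two-sided rank-sum p-values from group-1 rank sums. Exact (via pwilcox)
# for tie-free probes when the smaller group has <= `exact_limit` samples,
# else normal approximation with tie and continuity correction.
ranksum_p <- function(rank_sum1, n1, n2, info, exact_limit = 10L) {
  W <- rank_sum1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - info$tie3 / (n * (n - 1)))
  p <- rep(1, length(W))
  use_exact <- !info$has_ties & (min(n1, n2) <= exact_limit)
  if (any(use_exact)) {
    w <- W[use_exact]
    hi <- w > mu
    pe <- numeric(length(w))
    pe[hi] <- 2 * stats::pwilcox(w[hi] - 1, n1, n2, lower.tail = FALSE)
    pe[!hi] <- 2 * stats::pwilcox(w[!hi], n1, n2)
    p[use_exact] <- pmin(1, pe)
  }
  ap <- !use_exact & sigma2 > 0
  if (any(ap)) {
    z <- (abs(W[ap] - mu) - 0.5) / sqrt(sigma2[ap])
    p[ap] <- pmin(1, 2 * stats::pnorm(-pmax(z, 0)))
  }
  pmax(p, .Machine$double.xmin)
}

#' Per-CpG Wilcoxon rank-sum test
#'
#' Tests every probe for a two-group difference in beta values with the
#' two-sided Wilcoxon rank-sum test. The exact null distribution is used when
#' the smaller group has at most 10 samples and the probe has no tied values;
#' otherwise the normal approximation with continuity and tie correction is
#' used. Delta-beta is mean(group1) - mean(group2) with groups in sample-sheet
#' order.
#'
#' @param beta beta matrix (probes x samples), rownames = probe ids.
#' @param groups sample sheet (`sample_id`, `group`; exactly two groups).
#' @return a significance track: `data.frame` with columns `probe_id`, `p`,
#'   `delta_beta`, `rank`, plus attribute `N_total`; class `cpg_track`.
#' @seealso [cpg_ttest()], [rank_cpgs()]
#' @export
cpg_wilcoxon <- function(beta, groups) {
  g <- group_indices(beta, groups)
  info <- row_rank_info(beta[, c(g$idx1, g$idx2), drop = FALSE])
  n1 <- length(g$idx1)
  rs1 <- rowSums(info$R[, seq_len(n1), drop = FALSE])
  p <- ranksum_p(rs1, n1, length(g$idx2), info)
  db <- rowMeans(beta[, g$idx1, drop = FALSE]) -
    rowMeans(beta[, g$idx2, drop = FALSE])
  new_track(rownames(beta), p, db)
}

#' Per-CpG Welch t-test
#'
#' Two-sided Welch (unequal-variance) t-test per probe; an alternative input
#' test for the window scan. Probes with zero variance in both groups get
#' p = 1 when the means are equal and a machine-tiny p otherwise.
#'
#' @inheritParams cpg_wilcoxon
#' @return a `cpg_track` (see [cpg_wilcoxon()]).
#' @export
cpg_ttest <- function(beta, groups) {
  g <- group_indices(beta, groups)
  x1 <- beta[, g$idx1, drop = FALSE]; x2 <- beta[, g$idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, nrow(beta))
  ok <- se2 > 0
  tt <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  degenerate <- !ok & (m1 != m2)
  p[degenerate] <- .Machine$double.xmin
  new_track(rownames(beta), pmax(p, .Machine$double.xmin), m1 - m2)
}

new_track <- function(probe_id, p, delta_beta) {
  tr <- data.frame(probe_id = probe_id, p = p, delta_beta = delta_beta,
                   stringsAsFactors = FALSE)
  tr <- rank_cpgs(tr)
  tr
}

#' Assign significance ranks
#'
#' The rank of probe i is the number of probes at least as significant,
#' `#\{j : p_j <= p_i\}`; rank 1 means uniquely most significant, and tied
#' p-values all share the maximal count. This is the "max" tie rule, chosen
#' because it keeps the sequential hypergeometric bookkeeping of the window
#' score internally consistent (ranks count success cases). Idempotent and
#' invariant to input order.
#'
#' @param track data.frame with at least a `p` column.
#' @return the track with a `rank` column and attribute `N_total`; class
#'   `cpg_track`.
#' @export
rank_cpgs <- function(track) {
  stopifnot(is.data.frame(track), "p" %in% names(track))
  if (any(track$p <= 0 | track$p > 1)) stop("p-values must lie in (0, 1]")
  sp <- sort(track$p)
  track$rank <- findInterval(track$p, sp)   # count of p_j <= p_i
  attr(track, "N_total") <- nrow(track)
  class(track) <- unique(c("cpg_track", class(track)))
  track
}

#' Permutation estimate of the individual-CpG p-value cutoff
#'
#' Repeats the per-CpG test under random permutations of the group labels and
#' compares the permuted p-value distribution with the observed one to find
#' the largest p-value cutoff whose estimated FDR is at or below
#' `target_fdr`. For each candidate cutoff c (the sorted observed p-values),
#' `FDR(c) = mean_perm #\{p_perm < c\} / max(1, #\{p_obs < c\})`, monotonized
#' by a running maximum from small c before thresholding. If no cutoff
#' qualifies, the minimum observed p-value is returned with `n_below = 0` (the
#' caller then produces no candidate windows).
#'
#' @inheritParams cpg_wilcoxon
#' @param test `"wilcoxon"` or `"ttest"`.
#' @param target_fdr requested individual-CpG FDR level (default 0.10).
#' @param n_perm number of label permutations (>= 10).
#' @param seed integer seed for the permutations.
#' @return list of class `cutoff_estimate`: `cutoff`, `target_fdr`, `n_perm`,
#'   `n_below`, `seed`.
#' @export
permutation_fdr_cutoff <- function(beta, groups, test = c("wilcoxon", "ttest"),
                                   target_fdr = 0.10, n_perm = 20L, seed = 1L) {
  test <- match.arg(test)
  if (n_perm < 10L) stop("n_perm must be >= 10")
  g <- group_indices(beta, groups)
  n1 <- length(g$idx1); n2 <- length(g$idx2)
  cols <- c(g$idx1, g$idx2)
  if (test == "wilcoxon") {
    info <- row_rank_info(beta[, cols, drop = FALSE])
    p_obs <- ranksum_p(rowSums(info$R[, seq_len(n1), drop = FALSE]), n1, n2, info)
    perm_p <- with_seed(seed, {
      unlist(lapply(seq_len(n_perm), function(i) {
        pick <- sample(n1 + n2, n1)
        ranksum_p(rowSums(info$R[, pick, drop = FALSE]), n1, n2, info)
      }))
    })
  } else {
    sheet0 <- data.frame(sample_id = colnames(beta)[cols],
                         group = rep(c("a", "b"), c(n1, n2)))
    p_obs <- cpg_ttest(beta, sheet0)$p
    perm_p <- with_seed(seed, {
      unlist(lapply(seq_len(n_perm), function(i) {
        sh <- sheet0
        sh$group <- sample(sh$group)
        cpg_ttest(beta, sh)$p
      }))
    })
  }
  cand <- sort(unique(p_obs))
  sp_obs <- sort(p_obs)
  sp_perm <- sort(perm_p)
  n_obs <- findInterval(cand, sp_obs, left.open = TRUE)    # strict <
  n_perm_below <- findInterval(cand, sp_perm, left.open = TRUE) / n_perm
  fdr <- cummax(n_perm_below / pmax(1, n_obs))
  ok <- which(fdr <= target_fdr)
  if (length(ok) == 0L) {
    cutoff <- min(p_obs); n_below <- 0L
  } else {
    cutoff <- cand[max(ok)]
    n_below <- sum(p_obs < cutoff)
  }
  structure(list(cutoff = cutoff, target_fdr = target_fdr,
                 n_perm = as.integer(n_perm), n_below = as.integer(n_below),
                 seed = as.integer(seed)),
            class = "cutoff_estimate")
}

#' @export
print.cutoff_estimate <- function(x, ...) {
  cat("Permutation p-value cutoff: ", format(x$cutoff, digits = 4),
      " (target FDR ", x$target_fdr, ", ", x$n_perm, " permutations, ",
      x$n_below, " probes below cutoff)\n", sep = "")
  invisible(x)
}

#' Export a significance track as TSV
#'
#' @param track a `cpg_track`.
#' @param path output TSV path.
#' @export
write_track <- function(track, path) {
  utils::write.table(track[, c("probe_id", "p", "delta_beta", "rank")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Build a significance track from precomputed p-values
#'
#' Supports the workflow where per-CpG p-values come from a user-chosen model
#' (e.g. covariate-adjusted) rather than the built-in tests.
#'
#' @param probes a [probe_set()].
#' @param p per-probe p-values in (0, 1], aligned to `probes`.
#' @param delta_beta optional per-probe group-mean difference (default 0).
#' @return a `cpg_track`.
#' @export
precomputed_track <- function(probes, p, delta_beta = NULL) {
  stopifnot(length(p) == nrow(probes))
  if (is.null(delta_beta)) delta_beta <- rep(0, length(p))
  new_track(probes$probe_id, p, delta_beta)
}
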