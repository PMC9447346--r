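# CpG-membership contingency analyses: probe-in-region membership, Fisher
# odds ratios (e.g. DMR gaps vs X-inactivation escape genes), DMR-gap
# extraction per layer, and cross-condition DMR/gene overlap.

#' CpG membership in a region set
#'
#' @param probes a [probe_set()].
#' @param regions region data.frame (1-based inclusive); must be sorted and
#'   non-overlapping per chromosome.
#' @return logical vector: TRUE iff the probe position lies inside some
#'   region (boundaries inclusive).
#' @export
cpg_membership <- function(probes, regions) {
  if (nrow(regions) == 0L) return(rep(FALSE, nrow(probes)))
  member <- rep(FALSE, nrow(probes))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (any(r$start[-1] <= r$end[-nrow(r)])) {
      stop("regions must be non-overlapping within a chromosome")
    }
    pi <- which(probes$chrom == ch)
    if (length(pi) == 0L) next
    k <- findInterval(probes$pos[pi], r$start)
    member[pi] <- k > 0L & probes$pos[pi] <= r$end[pmax(k, 1L)]
  }
  member
}

#' Fisher odds ratio between two CpG memberships
#'
#' Forms the 2x2 table of joint memberships within a probe universe and runs
#' the two-sided Fisher exact test. The odds ratio is the conditional
#' maximum-likelihood estimate with an exact 95% confidence interval (the
#' convention that yields very wide intervals for sparse tables); the sample
#' cross-ratio ad/bc is reported alongside.
#'
#' @param membership_a,membership_b logical vectors aligned to the probe set.
#' @param universe logical mask restricting which probes enter the table
#'   (default all).
#' @return list of class `contingency_result`: `table` (2x2: a in rows),
#'   `or`, `ci_low`, `ci_high`, `p`, `or_sample`.
#' @export
fisher_or <- function(membership_a, membership_b, universe = NULL) {
  stopifnot(length(membership_a) == length(membership_b))
  if (is.null(universe)) universe <- rep(TRUE, length(membership_a))
  a <- membership_a[universe]; b <- membership_b[universe]
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2L, 2L, byrow = TRUE,
                dimnames = list(a = c("in", "out"), b = c("in", "out")))
  ft <- stats::fisher.test(tab)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(table = tab, or = unname(ft$estimate),
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                 p = ft$p.value, or_sample = or_sample),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("OR = %.4g (95%% CI %.4g-%.4g), p = %.3g (Fisher exact); sample OR %.4g\n",
              x$or, x$ci_low, x$ci_high, x$p, x$or_sample))
  print(x$table)
  invisible(x)
}

#' Gaps between a layer's DMRs within a chromosome span
#'
#' Returns the maximal intervals of `span` not covered by any region of the
#' layer; the gaps and the regions together partition the span exactly.
#'
#' @param layer region data.frame (one layer of a [dmrscale()] fit).
#' @param span single-row region data.frame (`chrom`, `start`, `end`)
#'   covering all of the layer's regions on that chromosome.
#' @return region data.frame of gaps (possibly empty).
#' @export
layer_gap_regions <- function(layer, span) {
  stopifnot(nrow(span) == 1L)
  sg <- regions_to_granges(span)
  lg <- regions_to_granges(layer[layer$chrom == span$chrom, , drop = FALSE])
  gaps <- GenomicRanges::setdiff(sg, lg)
  as_region_frame(gaps)
}

#' Cross-condition DMR and gene overlap
#'
#' Counts (i) region pairs between two DMR sets with any overlap, (ii) the
#' genes touched by each set, and (iii) the shared gene set — which can
#' include genes hit through non-overlapping parts of the gene body, overlap
#' the direct region comparison would miss.
#'
#' @param dmrs_a,dmrs_b region data.frames for two conditions.
#' @param genes gene intervals as a region data.frame with a `name` column
#'   (strand ignored; regions are unstranded).
#' @return list: `n_pairs`, `frac_a_overlapped`, `frac_b_overlapped`,
#'   `genes_a`, `genes_b`, `genes_shared`, `frac_genes_a_shared`,
#'   `frac_genes_b_shared`.
#' @export
condition_overlap <- function(dmrs_a, dmrs_b, genes = NULL) {
  ga <- regions_to_granges(dmrs_a); gb <- regions_to_granges(dmrs_b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  res <- list(n_pairs = length(hits),
              frac_a_overlapped = if (length(ga)) length(unique(S4Vectors::queryHits(hits))) / length(ga) else NA_real_,
              frac_b_overlapped = if (length(gb)) length(unique(S4Vectors::subjectHits(hits))) / length(gb) else NA_real_)
  if (!is.null(genes) && nrow(genes)) {
    gg <- regions_to_granges(genes)
    hit_a <- unique(genes$name[S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gg, ga))])
    hit_b <- unique(genes$name[S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gg, gb))])
    shared <- intersect(hit_a, hit_b)
    res$genes_a <- hit_a; res$genes_b <- hit_b; res$genes_shared <- shared
    res$frac_genes_a_shared <- if (length(hit_a)) length(shared) / length(hit_a) else NA_real_
    res$frac_genes_b_shared <- if (length(hit_b)) length(shared) / length(hit_b) else NA_real_
  }
  res
}
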