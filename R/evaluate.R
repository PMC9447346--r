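# Range-aware benchmarking of called DMRs against truth regions: width
# pairing, mapping values (fragmentation vs agglomeration), feature-level
# precision-recall with equal weight per truth region, AUCPR, and confusion
# metrics at feature/basepair/CpG resolution.

# fraction of each region in `of` covered by the union of `by`
coverage_fraction <- function(of, by) {
  if (length(by) == 0L || length(of) == 0L) return(rep(0, length(of)))
  byu <- GenomicRanges::reduce(by)
  hits <- GenomicRanges::findOverlaps(of, byu)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    of[S4Vectors::queryHits(hits)], byu[S4Vectors::subjectHits(hits)]))
  cov <- rep(0, length(of))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  cov[as.integer(names(agg))] <- as.numeric(agg)
  cov / GenomicRanges::width(of)
}

#' Pair truth and called region widths
#'
#' One pair per (truth, called) combination with at least 1 bp of overlap;
#' Pearson correlation is reported on log10 widths (the scale the size-class
#' benchmark spans) and on raw widths.
#'
#' @param truth,called region data.frames (`chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @return list with `pairs` (truth_width, called_width),
#'   `r_log10`, `r_raw` (NA when fewer than 2 pairs).
#' @export
pair_widths <- function(truth, called) {
  tg <- regions_to_granges(truth); cg <- regions_to_granges(called)
  hits <- GenomicRanges::findOverlaps(tg, cg)
  pairs <- data.frame(
    truth_width = GenomicRanges::width(tg)[S4Vectors::queryHits(hits)],
    called_width = GenomicRanges::width(cg)[S4Vectors::subjectHits(hits)])
  r_log10 <- r_raw <- NA_real_
  if (nrow(pairs) >= 2L) {
    r_log10 <- suppressWarnings(
      stats::cor(log10(pairs$truth_width), log10(pairs$called_width)))
    r_raw <- suppressWarnings(stats::cor(pairs$truth_width, pairs$called_width))
  }
  list(pairs = pairs, r_log10 = r_log10, r_raw = r_raw)
}

#' Mapping values: fragmentation vs agglomeration per truth region
#'
#' For each truth region with at least one overlapping called region, let a
#' be the number of called regions overlapping it and b the largest number of
#' truth regions sharing any of those called regions. The mapping value is a
#' (fragmentation, log > 0) or 1/b (agglomeration, log < 0), whichever is
#' further from 1 on the log scale; exactly 1 means clean one-to-one
#' recovery. Truth regions with no overlap are excluded from the value
#' distribution but counted in the one-to-one denominator.
#'
#' @inheritParams pair_widths
#' @return list with `values` (per overlapped truth region), `one_to_one`
#'   (fraction of ALL truth regions with value exactly 1), `n_unmatched`.
#' @export
mapping_values <- function(truth, called) {
  tg <- regions_to_granges(truth); cg <- regions_to_granges(called)
  hits <- GenomicRanges::findOverlaps(tg, cg)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  truth_per_called <- table(factor(s, levels = seq_along(cg)))
  vals <- vapply(unique(q), function(tj) {
    called_here <- s[q == tj]
    a <- length(called_here)
    b <- max(truth_per_called[called_here])
    if (abs(log10(a)) >= abs(log10(1 / b))) a else 1 / b
  }, numeric(1))
  list(values = vals,
       one_to_one = sum(vals == 1) / length(tg),
       n_unmatched = length(tg) - length(unique(q)))
}

#' Feature-level precision-recall curve and AUCPR
#'
#' Called regions are included stepwise from most to least significant. At
#' step n, precision is the mean over included called regions of the fraction
#' of each overlapping any truth region, and recall is the mean over all
#' truth regions of the fraction covered by the union of included called
#' regions (equal weight per truth region, so large regions do not dominate).
#' AUCPR is the trapezoid area over the recall axis with a prepended
#' (recall 0, first-step precision) point.
#'
#' @param truth region data.frame.
#' @param called region data.frame with a `p` (or `score`) column giving the
#'   inclusion order (ascending p; ties broken by input order).
#' @return list with `curve` (step, precision, recall) and `aucpr`.
#' @export
feature_pr_curve <- function(truth, called) {
  if (nrow(called) == 0L) {
    return(list(curve = data.frame(step = integer(), precision = double(),
                                   recall = double()), aucpr = 0))
  }
  ord <- if (!is.null(called$p)) order(called$p) else
    if (!is.null(called$score)) order(-called$score) else seq_len(nrow(called))
  called <- called[ord, , drop = FALSE]
  tg <- regions_to_granges(truth)
  cg <- regions_to_granges(called)
  frac_called <- coverage_fraction(cg, tg)
  n <- nrow(called)
  precision <- cumsum(frac_called) / seq_len(n)
  recall <- vapply(seq_len(n), function(k) {
    mean(coverage_fraction(tg, cg[seq_len(k)]))
  }, numeric(1))
  curve <- data.frame(step = seq_len(n), precision = precision,
                      recall = recall)
  r <- c(0, recall); p <- c(precision[1], precision)
  aucpr <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(curve = curve, aucpr = aucpr)
}

#' Confusion metrics at feature, basepair or CpG resolution
#'
#' At `bp` level, true/false positives and negatives are basepair counts
#' within the evaluable domain; at `cpg` level they are probe counts. At
#' `feature` level, precision and recall are the equal-weight fractional
#' measures of [feature_pr_curve()] evaluated at the full called set, with
#' fractional TP/FP/FN masses and the true-negative count taken as the number
#' of truth-free gap intervals of the domain untouched by any call (needed to
#' complete specificity and MCC at this level). `legacy = TRUE` additionally
#' reports specificity and MCC from the as-printed benchmark formulas
#' (specificity = (1 - FN)/N over negative features; MCC as a single ratio of
#' root products), which are non-standard and retained for comparison.
#'
#' @param truth,called region data.frames (1-based inclusive).
#' @param level `"feature"`, `"bp"` or `"cpg"`.
#' @param probes a [probe_set()]; required for `cpg` level and for the
#'   default domain.
#' @param domain evaluable span as a region data.frame; default: the probe
#'   span of each chromosome.
#' @param legacy also report the as-printed specificity/MCC variants.
#' @return list of class `metric_set`: `precision`, `recall`, `specificity`,
#'   `fdr`, `f1`, `mcc`, `level`, `counts` (TP/FP/FN/TN), and when
#'   `legacy = TRUE` also `specificity_legacy`, `mcc_legacy`.
#' @export
confusion_metrics <- function(truth, called, level = c("bp", "cpg", "feature"),
                              probes = NULL, domain = NULL, legacy = FALSE) {
  level <- match.arg(level)
  if (is.null(domain)) {
    if (is.null(probes)) stop("need probes or an explicit domain")
    domain <- probe_span(probes)
  }
  if (nrow(domain) == 0L) stop("empty evaluable domain")
  dg <- GenomicRanges::reduce(regions_to_granges(domain))
  tg <- GenomicRanges::intersect(regions_to_granges(truth), dg)
  cg <- GenomicRanges::intersect(regions_to_granges(called), dg)
  if (level == "bp") {
    tot <- sum(GenomicRanges::width(dg))
    tp <- sum(GenomicRanges::width(GenomicRanges::intersect(cg, tg)))
    fp <- sum(GenomicRanges::width(GenomicRanges::setdiff(cg, tg)))
    fn <- sum(GenomicRanges::width(GenomicRanges::setdiff(tg, cg)))
    tn <- tot - tp - fp - fn
  } else if (level == "cpg") {
    if (is.null(probes)) stop("cpg level needs probes")
    in_t <- cpg_membership(probes, as_region_frame(tg))
    in_c <- cpg_membership(probes, as_region_frame(cg))
    in_d <- cpg_membership(probes, as_region_frame(dg))
    tp <- sum(in_t & in_c & in_d); fp <- sum(!in_t & in_c & in_d)
    fn <- sum(in_t & !in_c & in_d); tn <- sum(!in_t & !in_c & in_d)
  } else {
    tgf <- regions_to_granges(truth); cgf <- regions_to_granges(called)
    frac <- coverage_fraction(cgf, tgf)
    cov <- coverage_fraction(tgf, cgf)
    tp <- sum(frac); fp <- sum(1 - frac); fn <- sum(1 - cov)
    gaps <- GenomicRanges::setdiff(dg, GenomicRanges::reduce(tgf))
    tn <- sum(S4Vectors::countQueryHits(
      GenomicRanges::findOverlaps(gaps, cgf)) == 0L)
  }
  res <- metrics_from_counts(tp, fp, fn, tn)
  res$level <- level
  res$counts <- c(TP = tp, FP = fp, FN = fn, TN = tn)
  if (legacy) {
    n_neg <- tn + fp
    fn_mean <- if (level == "feature") fn / max(1, length(regions_to_granges(truth))) else fn / max(1, fn + tp)
    res$specificity_legacy <- if (n_neg > 0) (1 - fn_mean) / n_neg else NA_real_
    q <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    num <- res$recall * res$specificity * res$precision * q
    den <- (1 - res$recall) * (1 - res$specificity) * (1 - res$precision) * (1 - q)
    res$mcc_legacy <- if (!is.na(den) && den > 0) sqrt(num) / sqrt(den) else
      ifelse(num > 0, Inf, NA_real_)
  }
  class(res) <- "metric_set"
  res
}

metrics_from_counts <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  list(precision = precision, recall = recall, specificity = specificity,
       fdr = 1 - precision, f1 = f1, mcc = mcc)
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("%s-level metrics: precision %.3f  recall %.3f  specificity %.3f  F1 %.3f  MCC %.3f\n",
              x$level, x$precision, x$recall, x$specificity, x$f1, x$mcc))
  invisible(x)
}

probe_span <- function(probes) {
  sp <- lapply(split(probes$pos, probes$chrom), range)
  data.frame(chrom = names(sp),
             start = vapply(sp, `[`, numeric(1), 1),
             end = vapply(sp, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}

as_region_frame <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Full benchmark of a called set against truth
#'
#' Convenience wrapper: width pairing, mapping values, the feature-level
#' precision-recall curve/AUCPR, and confusion metrics at all three levels.
#'
#' @param truth region data.frame.
#' @param called region data.frame with a `p` column (significance order).
#' @param probes a [probe_set()].
#' @return list with `widths`, `mapping`, `pr`, and `metrics` (per level).
#' @export
evaluate_calls <- function(truth, called, probes) {
  list(widths = pair_widths(truth, called),
       mapping = mapping_values(truth, called),
       pr = feature_pr_curve(truth, called),
       metrics = list(
         feature = confusion_metrics(truth, called, "feature", probes),
         bp = confusion_metrics(truth, called, "bp", probes),
         cpg = confusion_metrics(truth, called, "cpg", probes)))
}
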