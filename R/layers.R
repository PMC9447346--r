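# One layer of the scan: window placement, scoring, multiple-testing
# selection, merging, and the subtract-and-retest integration with the
# previous layer. Regions are carried internally as data.frames of global
# probe-row ranges (`first`, `last` index into the probe set), so all index
# arithmetic is adjacency in probe space, never basepairs.

#' Caller configuration
#'
#' @param windows increasing vector of adjacent-CpG window sizes, each >= 2.
#' @param locs_cutoff individual-CpG p-value threshold, or `"auto"` to
#'   estimate it with [permutation_fdr_cutoff()] at `locs_fdr`.
#' @param locs_fdr target FDR for the automatic cutoff (default 0.10).
#' @param region_cutoff adjusted region-significance threshold (default 0.01).
#' @param correction `"BY"` (Benjamini-Yekutieli) or `"bonferroni"`. The test
#'   count for either correction is the number of probes below `locs_cutoff`,
#'   not the number of windows.
#' @param n_perm permutations for the automatic cutoff.
#' @param seed seed for stochastic steps.
#' @return list of class `dmr_config`.
#' @export
dmr_config <- function(windows = c(4L, 8L, 16L, 32L, 64L),
                       locs_cutoff = "auto", locs_fdr = 0.10,
                       region_cutoff = 0.01,
                       correction = c("BY", "bonferroni"),
                       n_perm = 20L, seed = 1L) {
  correction <- match.arg(correction)
  windows <- as.integer(windows)
  if (any(windows < 2L) || any(diff(windows) <= 0L)) {
    stop("window sizes must be strictly increasing and >= 2")
  }
  if (!identical(locs_cutoff, "auto")) {
    locs_cutoff <- as.numeric(locs_cutoff)
    if (locs_cutoff <= 0 || locs_cutoff >= 1) stop("locs_cutoff must be in (0,1)")
  }
  if (region_cutoff <= 0 || region_cutoff >= 1) stop("region_cutoff must be in (0,1)")
  structure(list(windows = windows, locs_cutoff = locs_cutoff,
                 locs_fdr = locs_fdr, region_cutoff = region_cutoff,
                 correction = correction, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "dmr_config")
}

chrom_row_ranges <- function(probes) {
  idx <- split(seq_len(nrow(probes)), probes$chrom)
  idx[order(names(idx))]
}

# Shrink each region's row range to the span of its significant members, so
# a region's genomic extent runs from its first to its last member CpG
# rather than to the raw window edges.
trim_to_sig <- function(res, sig) {
  if (nrow(res) == 0L) return(res)
  for (i in seq_len(nrow(res))) {
    rows <- res$first[i]:res$last[i]
    sr <- rows[sig[rows]]
    if (length(sr)) {
      res$first[i] <- min(sr); res$last[i] <- max(sr)
    }
  }
  res
}

# Score a probe-row range using the individually-significant members only.
# The window statistic asks whether significant CpGs associate by adjacency;
# probes above the individual-CpG cutoff are not draws and contribute
# nothing. A range with < 2 significant members scores 1 (the conditioning
# draw exhausts the evidence).
score_sig_rows <- function(rows, track, sig, N) {
  r <- track$rank[rows[sig[rows]]]
  if (length(r) < 2L) return(0)
  score_region_log10(r, N)
}

#' Scan one window size across the genome
#'
#' Lays windows of `window_size` adjacent probes at stride 1 over each
#' chromosome independently (windows never cross chromosome boundaries;
#' chromosomes with fewer probes than the window are skipped). Windows
#' containing no probe with p below the individual-CpG cutoff are not
#' candidates; each candidate is scored with [score_region()] over the ranks
#' of its individually-significant members (the statistic measures whether
#' significant CpGs associate by adjacency; members above the cutoff are not
#' draws, so a window with a single significant probe scores 1).
#'
#' @param track a `cpg_track` aligned to `probes`.
#' @param probes a [probe_set()].
#' @param window_size count of adjacent probes per window.
#' @param locs_cutoff individual-CpG p-value threshold (numeric).
#' @return data.frame of scored candidate windows: `chrom`, `first`, `last`
#'   (global probe-set row numbers), `log10_p`, `p_region`.
#' @export
scan_layer <- function(track, probes, window_size, locs_cutoff) {
  stopifnot(nrow(track) == nrow(probes))
  N <- attr(track, "N_total")
  sig <- track$p < locs_cutoff
  out <- lapply(chrom_row_ranges(probes), function(rows) {
    n <- length(rows)
    if (n < window_size) return(NULL)
    s <- sig[rows]
    if (!any(s)) return(NULL)
    cs <- cumsum(c(0L, s))
    starts <- seq_len(n - window_size + 1L)
    cand <- starts[cs[starts + window_size] - cs[starts] > 0L]
    if (length(cand) == 0L) return(NULL)
    l10 <- vapply(cand, function(st) {
      score_sig_rows(rows[st:(st + window_size - 1L)], track, sig, N)
    }, numeric(1))
    data.frame(chrom = probes$chrom[rows[1]],
               first = rows[cand], last = rows[cand] + window_size - 1L,
               log10_p = l10, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_window_frame()
  rownames(res) <- NULL
  res$p_region <- pmax(10^res$log10_p, .Machine$double.xmin)
  res
}

empty_window_frame <- function() {
  data.frame(chrom = character(), first = integer(), last = integer(),
             log10_p = double(), p_region = double(), stringsAsFactors = FALSE)
}

#' Multiple-testing correction and selection of windows
#'
#' Adjusts candidate window scores treating the number of tests as the count
#' of probes below the individual-CpG cutoff (`n_tests`), then keeps windows
#' with adjusted p below the region cutoff. Bonferroni multiplies by
#' `n_tests`; Benjamini-Yekutieli applies the step-up rule with `n_tests`
#' as the family size (candidates beyond the observed ones enter as p = 1
#' placeholders, which is [stats::p.adjust()]'s behaviour for `n` larger than
#' the input length).
#'
#' @param windows data.frame from [scan_layer()].
#' @param config a [dmr_config()].
#' @param n_tests number of probes with p below the individual-CpG cutoff.
#' @return the retained windows with a `p_adjusted` column.
#' @export
adjust_and_select <- function(windows, config, n_tests) {
  if (nrow(windows) == 0L || n_tests == 0L) {
    w <- empty_window_frame(); w$p_adjusted <- double(); return(w)
  }
  windows$p_adjusted <- adjust_pvec(windows$p_region, config, n_tests)
  windows[windows$p_adjusted < config$region_cutoff, , drop = FALSE]
}

adjust_pvec <- function(p, config, n_tests) {
  if (config$correction == "bonferroni") {
    pmin(1, p * n_tests)
  } else {
    stats::p.adjust(p, method = "BY", n = max(n_tests, length(p)))
  }
}

# Adjusted significance for a single rescored region, used by the
# integration retest: the most conservative (rank-1) form of the same rule.
single_region_significant <- function(log10_p, config, n_tests) {
  if (n_tests == 0L) return(FALSE)
  adj <- log10_p + log10(n_tests) +
    if (config$correction == "BY") log10(sum(1 / seq_len(n_tests))) else 0
  adj < log10(config$region_cutoff)
}

#' Merge adjacent significant windows into tentative regions
#'
#' Windows whose probe-index ranges overlap or abut (gap 0 in index space)
#' are unioned; each merged region is rescored with [score_region()] so the
#' merged unit carries a comparable score into integration.
#'
#' @param selected selected windows from [adjust_and_select()].
#' @param track the `cpg_track` used for scoring.
#' @param locs_cutoff individual-CpG p-value threshold defining which members
#'   enter the rescore.
#' @return data.frame of tentative regions (`chrom`, `first`, `last`,
#'   `log10_p`, `p_region`).
#' @export
merge_adjacent <- function(selected, track, locs_cutoff) {
  if (nrow(selected) == 0L) return(empty_window_frame())
  N <- attr(track, "N_total")
  sig <- track$p < locs_cutoff
  out <- lapply(split(selected, selected$chrom), function(w) {
    w <- w[order(w$first), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(w$first[-1] > cummax(w$last)[-nrow(w)] + 1L)))
    first <- tapply(w$first, grp, min)
    last <- tapply(w$last, grp, max)
    data.frame(chrom = w$chrom[1], first = as.integer(first),
               last = as.integer(last), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- trim_to_sig(res, sig)
  res$log10_p <- vapply(seq_len(nrow(res)), function(i) {
    score_sig_rows(res$first[i]:res$last[i], track, sig, N)
  }, numeric(1))
  res$p_region <- pmax(10^res$log10_p, .Machine$double.xmin)
  res[order(res$chrom, res$first), , drop = FALSE]
}

#' Integrate a layer with the previous layer
#'
#' For each tentative region of the new (larger-window) layer, every
#' overlapping previous-layer region is removed from it in turn and the
#' remainder rescored; the tentative region survives only if every remainder
#' is still significant under the layer's adjusted-significance rule (an
#' empty remainder counts as non-significant). A surviving region absorbs its
#' overlapping previous-layer regions (union of probe indices); otherwise the
#' previous-layer regions stand in its place. Previous-layer regions
#' overlapping no tentative region are carried through unchanged. This keeps
#' broader regions only when no single smaller region explains their
#' significance, so regions are added, expanded or consolidated across
#' layers but never lost.
#'
#' @param prev_layer data.frame of previous-layer regions (internally
#'   non-overlapping).
#' @param next_candidates data.frame of merged tentative regions.
#' @param track the `cpg_track`.
#' @param config a [dmr_config()].
#' @param n_tests probes below the individual-CpG cutoff.
#' @param locs_cutoff individual-CpG p-value threshold defining scored members.
#' @return data.frame of integrated regions.
#' @export
integrate_layers <- function(prev_layer, next_candidates, track, config,
                             n_tests, locs_cutoff) {
  N <- attr(track, "N_total")
  sig <- track$p < locs_cutoff
  if (nrow(prev_layer) == 0L) return(next_candidates)
  kept <- list(); absorbed <- rep(FALSE, nrow(prev_layer))
  if (nrow(next_candidates)) {
    for (i in seq_len(nrow(next_candidates))) {
      cand <- next_candidates[i, ]
      ov <- which(prev_layer$chrom == cand$chrom &
                    prev_layer$first <= cand$last &
                    prev_layer$last >= cand$first)
      if (length(ov) == 0L) { kept[[length(kept) + 1L]] <- cand; next }
      all_sig <- TRUE
      for (j in ov) {
        rem <- setdiff(cand$first:cand$last,
                       prev_layer$first[j]:prev_layer$last[j])
        if (length(rem) == 0L ||
            !single_region_significant(score_sig_rows(rem, track, sig, N),
                                       config, n_tests)) {
          all_sig <- FALSE
          break
        }
      }
      if (all_sig) {
        merged <- data.frame(chrom = cand$chrom,
                             first = min(cand$first, prev_layer$first[ov]),
                             last = max(cand$last, prev_layer$last[ov]),
                             stringsAsFactors = FALSE)
        absorbed[ov] <- TRUE
        kept[[length(kept) + 1L]] <- merged[, c("chrom", "first", "last")]
      }
      # rejected candidate: overlapping prev regions propagate via !absorbed
    }
  }
  carry <- prev_layer[!absorbed, c("chrom", "first", "last"), drop = FALSE]
  pieces <- c(kept, list(carry))
  pieces <- lapply(pieces, function(d) d[, c("chrom", "first", "last"), drop = FALSE])
  res <- do.call(rbind, pieces)
  res <- res[order(res$chrom, res$first), , drop = FALSE]
  # union any residual overlaps (a prev region absorbed by one candidate can
  # also overlap another); overlap only, abutting regions stay distinct
  out <- lapply(split(res, res$chrom), function(w) {
    grp <- cumsum(c(1L, as.integer(w$first[-1] > cummax(w$last)[-nrow(w)])))
    data.frame(chrom = w$chrom[1],
               first = as.integer(tapply(w$first, grp, min)),
               last = as.integer(tapply(w$last, grp, max)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- trim_to_sig(res, sig)
  res$log10_p <- vapply(seq_len(nrow(res)), function(i) {
    score_sig_rows(res$first[i]:res$last[i], track, sig, N)
  }, numeric(1))
  res$p_region <- pmax(10^res$log10_p, .Machine$double.xmin)
  res[order(res$chrom, res$first), , drop = FALSE]
}
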