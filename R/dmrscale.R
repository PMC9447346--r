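#' Call differentially methylated regions across scales
#'
#' Fits the scale-aware DMR model: per-CpG two-group significance is ranked,
#' windows of increasing adjacent-CpG counts are scored with the sequential
#' hypergeometric statistic ([score_region()]), significant windows are
#' selected under Benjamini-Yekutieli or Bonferroni control (test count =
#' probes below the individual-CpG cutoff), merged, and successive layers are
#' integrated by subtract-and-retest ([integrate_layers()]) so every
#' lower-layer region nests inside exactly one upper-layer region. The top
#' layer is the primary output; the full hierarchy is retained.
#'
#' @param beta beta matrix (probes x samples, values in \[0,1\]), rows in
#'   probe-set order. Not needed when `test = "precomputed"`.
#' @param probes a [probe_set()].
#' @param groups sample sheet (`sample_id`, `group`); two groups, >= 2 each.
#' @param config a [dmr_config()]; controls windows, cutoffs and correction.
#' @param test `"wilcoxon"` (default), `"ttest"`, or `"precomputed"`.
#' @param track a precomputed `cpg_track` (required for
#'   `test = "precomputed"`; otherwise computed from `beta`).
#' @return object of class `dmrscale`: list with `layers` (one data.frame of
#'   regions per window size; columns `chrom, start, end, first_index,
#'   last_index, n_cpgs, p_region, log10_p_region, p_adjusted, layer,
#'   mean_delta_beta`), `links` (child/parent containment edges between
#'   consecutive layers), `track`, `probes`, `config`, `cutoff` (the
#'   individual-CpG cutoff used, with provenance), and `n_tests`.
#' @examples
#' sim <- simulate_methylation(backbone_config(n_probes = 3000, n_samples = 12),
#'                             sim_config(n_per_group = 4, n_dmrs_per_class = 2),
#'                             seed = 7)
#' fit <- dmrscale(sim$beta, sim$probes, sim$groups,
#'                 config = dmr_config(windows = c(4, 8), locs_cutoff = 0.01,
#'                                     n_perm = 10))
#' fit
#' @export
dmrscale <- function(beta = NULL, probes, groups = NULL,
                     config = dmr_config(),
                     test = c("wilcoxon", "ttest", "precomputed"),
                     track = NULL) {
  test <- match.arg(test)
  if (test == "precomputed") {
    if (is.null(track)) stop("test = 'precomputed' requires a track")
  } else {
    if (is.null(beta) || is.null(groups)) stop("beta and groups required")
    stopifnot(nrow(beta) == nrow(probes))
    track <- if (test == "wilcoxon") cpg_wilcoxon(beta, groups) else
      cpg_ttest(beta, groups)
  }
  stopifnot(nrow(track) == nrow(probes))

  if (identical(config$locs_cutoff, "auto")) {
    if (is.null(beta) || is.null(groups)) {
      stop("automatic cutoff needs beta and groups (or set locs_cutoff)")
    }
    cutoff <- permutation_fdr_cutoff(beta, groups,
                                     test = if (test == "ttest") "ttest" else "wilcoxon",
                                     target_fdr = config$locs_fdr,
                                     n_perm = config$n_perm, seed = config$seed)
  } else {
    cutoff <- structure(list(cutoff = config$locs_cutoff, target_fdr = NA_real_,
                             n_perm = 0L, n_below = sum(track$p < config$locs_cutoff),
                             seed = config$seed),
                        class = "cutoff_estimate")
  }
  n_tests <- sum(track$p < cutoff$cutoff)

  layers <- vector("list", length(config$windows))
  prev <- NULL
  for (li in seq_along(config$windows)) {
    w <- config$windows[li]
    cand <- if (n_tests == 0L) empty_window_frame() else
      merge_adjacent(adjust_and_select(scan_layer(track, probes, w,
                                                  cutoff$cutoff),
                                       config, n_tests),
                     track, cutoff$cutoff)
    layer <- if (li == 1L || is.null(prev)) cand else
      integrate_layers(prev, cand, track, config, n_tests, cutoff$cutoff)
    layers[[li]] <- layer
    prev <- layer
  }

  records <- lapply(seq_along(layers), function(li) {
    region_records(layers[[li]], probes, track, li, config, n_tests)
  })
  names(records) <- paste0("layer_", config$windows)
  fit <- structure(list(layers = records, links = layer_links(layers),
                        track = track, probes = probes, config = config,
                        cutoff = cutoff, n_tests = n_tests),
                   class = "dmrscale")
  fit
}

region_records <- function(layer, probes, track, layer_index, config, n_tests) {
  if (is.null(layer) || nrow(layer) == 0L) return(empty_dmr_frame())
  # correction re-applied within the layer over the merged regions' rescored
  # p-values, with the probe-based family size
  p_adj <- adjust_pvec(layer$p_region, config, n_tests)
  data.frame(chrom = layer$chrom,
             start = probes$pos[layer$first],
             end = probes$pos[layer$last],
             first_index = probes$index[layer$first],
             last_index = probes$index[layer$last],
             n_cpgs = layer$last - layer$first + 1L,
             p_region = layer$p_region,
             log10_p_region = layer$log10_p,
             p_adjusted = pmax(p_adj, layer$p_region),
             layer = layer_index,
             mean_delta_beta = vapply(seq_len(nrow(layer)), function(i) {
               mean(track$delta_beta[layer$first[i]:layer$last[i]])
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

layer_links <- function(layers) {
  out <- list()
  for (li in seq_along(layers)[-1]) {
    lo <- layers[[li - 1L]]; hi <- layers[[li]]
    if (is.null(lo) || nrow(lo) == 0L || is.null(hi) || nrow(hi) == 0L) next
    parent <- vapply(seq_len(nrow(lo)), function(i) {
      hit <- which(hi$chrom == lo$chrom[i] & hi$first <= lo$first[i] &
                     hi$last >= lo$last[i])
      if (length(hit) == 1L) hit else NA_integer_
    }, integer(1))
    out[[length(out) + 1L]] <- data.frame(child_layer = li - 1L,
                                          child_id = seq_len(nrow(lo)),
                                          parent_layer = li,
                                          parent_id = parent)
  }
  if (length(out) == 0L) {
    return(data.frame(child_layer = integer(), child_id = integer(),
                      parent_layer = integer(), parent_id = integer()))
  }
  do.call(rbind, out)
}

#' @export
print.dmrscale <- function(x, ...) {
  cat("Scale-aware DMR fit\n")
  cat("  probes:", nrow(x$probes), "on",
      length(unique(x$probes$chrom)), "chromosome(s)\n")
  cat("  individual-CpG cutoff:", format(x$cutoff$cutoff, digits = 4),
      sprintf("(%d probes below; %s correction, region cutoff %g)\n",
              x$n_tests, x$config$correction, x$config$region_cutoff))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d (%2d adj. CpGs): %4d region(s), %s bp covered\n",
                i, x$config$windows[i], nrow(l),
                format(sum(l$end - l$start + 1), big.mark = ",")))
  }
  invisible(x)
}

#' @export
summary.dmrscale <- function(object, ...) {
  tab <- do.call(rbind, lapply(seq_along(object$layers), function(i) {
    l <- object$layers[[i]]
    data.frame(layer = i, window = object$config$windows[i],
               n_regions = nrow(l),
               n_cpgs_covered = sum(l$n_cpgs),
               bp_covered = sum(l$end - l$start + 1),
               median_width = if (nrow(l)) stats::median(l$end - l$start + 1) else NA_real_)
  }))
  structure(list(layers = tab, cutoff = object$cutoff,
                 n_tests = object$n_tests), class = "summary.dmrscale")
}

#' @export
print.summary.dmrscale <- function(x, ...) {
  print(x$cutoff)
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Extract one layer of called regions
#'
#' @param x a `dmrscale` fit.
#' @param row.names,optional unused, for the generic.
#' @param layer layer index; default the top (largest-window) layer.
#' @param ... unused.
#' @return data.frame of region records.
#' @export
as.data.frame.dmrscale <- function(x, row.names = NULL, optional = FALSE,
                                   layer = length(x$layers), ...) {
  x$layers[[layer]]
}

#' Plot the layer hierarchy of a fit
#'
#' Draws each layer's regions as horizontal segments along the genome
#' (one track per layer, chromosomes concatenated), visualizing how smaller
#' regions consolidate into larger ones up the hierarchy.
#'
#' @param x a `dmrscale` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dmrscale <- function(x, ...) {
  chroms <- unique(x$probes$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) {
    max(x$probes$pos[x$probes$chrom == ch]) + 1e5
  }, numeric(1))))
  names(offs) <- c(chroms, "end")
  nl <- length(x$layers)
  graphics::plot(NULL, xlim = c(0, offs[length(offs)]), ylim = c(0.5, nl + 0.5),
                 xlab = "concatenated genomic position (bp)", ylab = "layer",
                 yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nl),
                 labels = paste0(x$config$windows, " CpG"))
  for (i in seq_len(nl)) {
    l <- x$layers[[i]]
    if (nrow(l) == 0L) next
    x0 <- offs[l$chrom] + l$start
    x1 <- offs[l$chrom] + l$end
    graphics::segments(x0, i, x1, i, lwd = 4)
  }
  invisible(x)
}

#' Write all layers, the hierarchy and run metadata to a directory
#'
#' Emits per-layer BED + TSV (via [write_dmrs()]), a hierarchy edge list TSV,
#' and a JSON run-metadata record.
#'
#' @param fit a `dmrscale` fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_dmrscale <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fit$layers)) {
    base <- file.path(dir, sprintf("layer_%02d_w%d", i, fit$config$windows[i]))
    write_dmrs(fit$layers[[i]], paste0(base, ".bed"), paste0(base, ".tsv"))
  }
  utils::write.table(fit$links, file.path(dir, "hierarchy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(windows = fit$config$windows,
               correction = fit$config$correction,
               region_cutoff = fit$config$region_cutoff,
               locs_cutoff = fit$cutoff$cutoff,
               locs_cutoff_n_perm = fit$cutoff$n_perm,
               n_tests = fit$n_tests,
               seed = fit$config$seed,
               n_probes = nrow(fit$probes),
               n_regions = vapply(fit$layers, nrow, integer(1)))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
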