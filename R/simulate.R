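# DMR-injection simulator: an array-like synthetic backbone (clustered +
# sparse probe spacing, bimodal beta values, per-probe sample dispersion)
# plus injection of ground-truth DMRs under size-class CpG constraints,
# interior noise masking, delta-beta inflation and max-rescaling.

#' Backbone generator configuration
#'
#' Describes the synthetic methylation-array backbone: probe layout and the
#' beta-value model. Probe spacing mixes CpG-island-like short gaps with
#' sparse background gaps; per-probe baselines are drawn from a bimodal Beta
#' mixture (modes near 0.06 and 0.94 with a minor intermediate component),
#' and samples scatter around the baseline with standard deviation
#' `dispersion * sqrt(b(1-b))`, clipped to \[0,1\].
#'
#' @param n_probes total probes across all chromosomes.
#' @param n_samples number of samples.
#' @param n_chroms number of chromosomes (probes split evenly).
#' @param island_prob probability a gap is island-like (short).
#' @param island_gap,background_gap mean gap sizes in bp for the two states.
#' @param mix_weights weights of the (low, high, intermediate) baseline
#'   components.
#' @param dispersion between-sample dispersion scale; 0 gives identical
#'   samples at each probe.
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(n_probes = 50000L, n_samples = 16L,
                            n_chroms = 4L, island_prob = 0.7,
                            island_gap = 150, background_gap = 9000,
                            mix_weights = c(0.45, 0.45, 0.10),
                            dispersion = 0.15) {
  structure(list(n_probes = as.integer(n_probes),
                 n_samples = as.integer(n_samples),
                 n_chroms = as.integer(n_chroms), island_prob = island_prob,
                 island_gap = island_gap, background_gap = background_gap,
                 mix_weights = mix_weights / sum(mix_weights),
                 dispersion = dispersion),
            class = "backbone_config")
}

#' Generate a synthetic array backbone
#'
#' @param config a [backbone_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `probes` (a [probe_set()]) and `beta` (probes x samples
#'   matrix in \[0,1\]).
#' @export
generate_backbone <- function(config = backbone_config(), seed = 1L) {
  with_seed(seed, {
    per <- diff(round(seq(0, config$n_probes, length.out = config$n_chroms + 1L)))
    pieces <- lapply(seq_len(config$n_chroms), function(ci) {
      n <- per[ci]
      isl <- stats::runif(n) < config$island_prob
      gaps <- ifelse(isl,
                     1 + stats::rpois(n, config$island_gap),
                     1 + round(stats::rexp(n, 1 / config$background_gap)))
      data.frame(chrom = sprintf("chr%d", ci), pos = cumsum(gaps) + 1000L)
    })
    layout <- do.call(rbind, pieces)
    probes <- probe_set(sprintf("cg%07d", seq_len(nrow(layout))),
                        layout$chrom, layout$pos)
    comp <- sample.int(3L, nrow(probes), replace = TRUE,
                       prob = config$mix_weights)
    base <- numeric(nrow(probes))
    base[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 18)
    base[comp == 2L] <- stats::rbeta(sum(comp == 2L), 18, 2)
    base[comp == 3L] <- stats::rbeta(sum(comp == 3L), 4, 4)
    sd <- config$dispersion * sqrt(base * (1 - base))
    beta <- base + matrix(stats::rnorm(nrow(probes) * config$n_samples),
                          nrow(probes)) * sd
    beta <- pmax(pmin(beta, 1), 0)   # matrix first so dims survive pmin/pmax
    dimnames(beta) <- list(probes$probe_id,
                           sprintf("S%02d", seq_len(config$n_samples)))
    list(probes = probes, beta = beta)
  })
}

#' Simulation configuration
#'
#' Defaults mirror the benchmark design: two groups of 8 samples, four
#' decade-wide size classes with minimum CpG counts 3/6/9/12, injected DMRs
#' at least 10 probes apart, half the interior CpGs masked (noise 0.5) and a
#' beta offset of 0.2 added to the higher-methylated group.
#'
#' @param n_per_group samples per group.
#' @param size_classes data.frame with `min_bp`, `max_bp`, `min_cpgs`.
#' @param n_dmrs_per_class DMRs injected per size class.
#' @param spacing_cpgs minimum probe gap between injected DMRs.
#' @param noise fraction of interior CpGs masked (kept at original beta).
#' @param delta_beta beta offset added to non-masked CpGs of the
#'   higher-mean group.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 8L,
                       size_classes = default_size_classes(),
                       n_dmrs_per_class = 25L, spacing_cpgs = 10L,
                       noise = 0.5, delta_beta = 0.2) {
  stopifnot(noise >= 0, noise < 1, delta_beta > 0, delta_beta < 1)
  structure(list(n_per_group = as.integer(n_per_group),
                 size_classes = size_classes,
                 n_dmrs_per_class = as.integer(n_dmrs_per_class),
                 spacing_cpgs = as.integer(spacing_cpgs),
                 noise = noise, delta_beta = delta_beta),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_size_classes <- function() {
  data.frame(min_bp = c(100, 1e3, 1e4, 1e5), max_bp = c(1e3, 1e4, 1e5, 1e6),
             min_cpgs = c(3L, 6L, 9L, 12L))
}

#' Randomly split samples into two groups
#'
#' @param sample_ids pool of sample ids.
#' @param n_per_group samples drawn without replacement into each group.
#' @param seed integer seed.
#' @return sample sheet data.frame (`sample_id`, `group` in Group1/Group2).
#' @export
assign_groups <- function(sample_ids, n_per_group, seed = 1L) {
  if (length(sample_ids) < 2L * n_per_group) {
    stop("sample pool (", length(sample_ids), ") too small for two groups of ",
         n_per_group)
  }
  with_seed(seed, {
    pick <- sample(sample_ids, 2L * n_per_group)
    data.frame(sample_id = pick,
               group = rep(c("Group1", "Group2"), each = n_per_group),
               stringsAsFactors = FALSE)
  })
}

#' Sample non-overlapping regions for DMR injection
#'
#' Region sizes are drawn log-uniformly within each size class and snapped to
#' the member probe span; a placement is accepted only if the span stays in
#' its class, the member-CpG count meets the class minimum, and the region is
#' at least `spacing_cpgs` probes away from every previously accepted region.
#'
#' @param probes a [probe_set()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame with `chrom`, `start`, `end`, `first_row`, `last_row`
#'   (global probe-set rows), `n_cpgs`, `size_class`.
#' @export
sample_dmr_regions <- function(probes, config = sim_config(), seed = 1L) {
  sc <- config$size_classes
  with_seed(seed, {
    taken_lo <- integer(0); taken_hi <- integer(0)
    out <- list()
    for (cl in seq_len(nrow(sc))) {
      placed <- 0L
      attempts <- 0L
      max_attempts <- 500L * max(1L, config$n_dmrs_per_class)
      while (placed < config$n_dmrs_per_class && attempts < max_attempts) {
        attempts <- attempts + 1L
        size <- 10^stats::runif(1, log10(sc$min_bp[cl]), log10(sc$max_bp[cl]))
        a <- sample.int(nrow(probes), 1L)
        ch <- probes$chrom[a]
        hi <- a
        lim <- probes$pos[a] + size - 1
        while (hi < nrow(probes) && probes$chrom[hi + 1L] == ch &&
               probes$pos[hi + 1L] <= lim) hi <- hi + 1L
        n_cpg <- hi - a + 1L
        span <- probes$pos[hi] - probes$pos[a] + 1L
        if (n_cpg < sc$min_cpgs[cl] || span < sc$min_bp[cl] ||
            span >= sc$max_bp[cl]) next
        gap <- config$spacing_cpgs
        if (any(a <= taken_hi + gap & hi >= taken_lo - gap)) next
        taken_lo <- c(taken_lo, a); taken_hi <- c(taken_hi, hi)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = probes$pos[a], end = probes$pos[hi],
          first_row = a, last_row = hi, n_cpgs = n_cpg, size_class = cl,
          stringsAsFactors = FALSE)
        placed <- placed + 1L
      }
      if (placed < config$n_dmrs_per_class) {
        stop("could not place ", config$n_dmrs_per_class,
             " regions for size class ", cl, " (", sc$min_bp[cl], "-",
             sc$max_bp[cl], " bp); placed ", placed)
      }
    }
    if (length(out) == 0L) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), first_row = integer(),
                        last_row = integer(), n_cpgs = integer(),
                        size_class = integer(), stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    res[order(res$chrom, res$start), , drop = FALSE]
  })
}

#' Inject differential methylation into truth regions
#'
#' For each region, `round(noise * interior)` interior CpGs (never the first
#' or last member) are masked and left untouched; the group with the greater
#' mean beta over the region's members has `delta_beta` added to every
#' non-masked member CpG; any probe pushed above 1 has all samples' beta
#' divided by that probe's maximum, restoring the \[0,1\] range.
#'
#' @param beta beta matrix.
#' @param groups sample sheet with two groups.
#' @param regions regions from [sample_dmr_regions()].
#' @param config a [sim_config()] (supplies `noise` and `delta_beta`).
#' @param seed integer seed for the masking draw.
#' @return list with `beta` (modified matrix) and `regions` (input plus
#'   `inflated_group` and a `masked_rows` list-column of global probe rows).
#' @export
inject_dmrs <- function(beta, groups, regions, config = sim_config(),
                        seed = 1L) {
  g <- group_indices(beta, groups)
  masked_rows <- vector("list", nrow(regions))
  inflated <- character(nrow(regions))
  with_seed(seed, {
    for (i in seq_len(nrow(regions))) {
      rows <- regions$first_row[i]:regions$last_row[i]
      interior <- setdiff(rows, range(rows))
      n_mask <- floor(config$noise * length(interior) + 0.5)
      masked <- if (n_mask > 0L) {
        sort(interior[sample.int(length(interior), n_mask)])
      } else integer(0)
      masked_rows[[i]] <- masked
      open <- setdiff(rows, masked)
      m1 <- mean(beta[rows, g$idx1]); m2 <- mean(beta[rows, g$idx2])
      target <- if (m1 >= m2) g$idx1 else g$idx2
      inflated[i] <- if (m1 >= m2) g$levels[1] else g$levels[2]
      beta[open, target] <- beta[open, target] + config$delta_beta
      over <- open[apply(beta[open, , drop = FALSE], 1L, max) > 1]
      for (r in over) beta[r, ] <- beta[r, ] / max(beta[r, ])
    }
  })
  regions$inflated_group <- inflated
  regions$masked_rows <- I(masked_rows)
  list(beta = beta, regions = regions)
}

#' Simulate a full benchmark dataset
#'
#' Composes backbone generation (or a user-supplied real beta matrix), random
#' group assignment, truth-region sampling and DMR injection.
#'
#' @param backbone a [backbone_config()], or a list with `probes` and `beta`
#'   for a pre-built (e.g. real-data) backbone.
#' @param config a [sim_config()].
#' @param seed integer master seed; sub-steps derive their own seeds from it.
#' @return list with `probes`, `beta`, `groups`, `truth` (regions with
#'   masking/inflation records), `config`, `seed`.
#' @export
simulate_methylation <- function(backbone = backbone_config(),
                                 config = sim_config(), seed = 1L) {
  bb <- if (inherits(backbone, "backbone_config")) {
    generate_backbone(backbone, seed = seed)
  } else {
    stopifnot(is.list(backbone), !is.null(backbone$probes), !is.null(backbone$beta))
    backbone
  }
  groups <- assign_groups(colnames(bb$beta), config$n_per_group,
                          seed = seed + 1L)
  regions <- sample_dmr_regions(bb$probes, config, seed = seed + 2L)
  inj <- inject_dmrs(bb$beta, groups, regions, config, seed = seed + 3L)
  list(probes = bb$probes, beta = inj$beta, groups = groups,
       truth = inj$regions, config = config, seed = as.integer(seed))
}

#' Write simulation truth and parameters to a directory
#'
#' @param sim result of [simulate_methylation()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim$truth
  bed <- data.frame(chrom = tr$chrom, start = tr$start - 1L, end = tr$end,
                    name = sprintf("truth_%03d_class%d", seq_len(nrow(tr)),
                                   tr$size_class))
  utils::write.table(bed, file.path(dir, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  params <- list(n_per_group = sim$config$n_per_group,
                 n_dmrs_per_class = sim$config$n_dmrs_per_class,
                 spacing_cpgs = sim$config$spacing_cpgs,
                 noise = sim$config$noise, delta_beta = sim$config$delta_beta,
                 seed = sim$seed, n_probes = nrow(sim$probes),
                 n_truth = nrow(tr))
  jsonlite::write_json(params, file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
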