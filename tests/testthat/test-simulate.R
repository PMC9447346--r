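test_that("backbone generation is reproducible with bimodal beta values", {
  cfg <- backbone_config(n_probes = 3000, n_samples = 6)
  b1 <- generate_backbone(cfg, seed = 2)
  b2 <- generate_backbone(cfg, seed = 2)
  expect_identical(b1, b2)
  expect_true(all(b1$beta >= 0 & b1$beta <= 1))
  # bimodal: both extreme bins dominate the middle
  h <- hist(b1$beta, breaks = seq(0, 1, 0.1), plot = FALSE)$counts
  expect_gt(h[1] + h[2], h[5] + h[6])
  expect_gt(h[9] + h[10], h[5] + h[6])
  # zero dispersion collapses samples onto the probe baseline
  b0 <- generate_backbone(backbone_config(n_probes = 500, n_samples = 4,
                                          dispersion = 0), seed = 2)
  expect_true(all(apply(b0$beta, 1, function(v) max(v) - min(v)) == 0))
})

test_that("probe layout mixes clustered and sparse spacing", {
  bb <- generate_backbone(backbone_config(n_probes = 5000, n_samples = 2),
                          seed = 4)
  gaps <- unlist(tapply(bb$probes$pos, bb$probes$chrom, diff))
  expect_gt(mean(gaps < 500), 0.4)    # island-like gaps
  expect_gt(mean(gaps > 2000), 0.1)   # sparse background
})

test_that("group assignment draws disjoint groups and validates the pool", {
  ids <- sprintf("S%02d", 1:53)
  g <- assign_groups(ids, 8, seed = 5)
  expect_equal(nrow(g), 16L)
  expect_equal(as.integer(table(g$group)), c(8L, 8L))
  expect_false(any(duplicated(g$sample_id)))
  expect_identical(g, assign_groups(ids, 8, seed = 5))
  expect_error(assign_groups(ids[1:15], 8), "too small")
})

test_that("sampled truth regions respect size-class, count and spacing constraints", {
  bb <- generate_backbone(backbone_config(n_probes = 20000, n_samples = 2),
                          seed = 6)
  cfg <- sim_config(n_dmrs_per_class = 5)
  reg <- sample_dmr_regions(bb$probes, cfg, seed = 6)
  expect_equal(nrow(reg), 20L)
  sc <- cfg$size_classes
  for (i in seq_len(nrow(reg))) {
    cl <- reg$size_class[i]
    span <- reg$end[i] - reg$start[i] + 1L
    expect_gte(span, sc$min_bp[cl])
    expect_lt(span, sc$max_bp[cl])
    expect_gte(reg$n_cpgs[i], sc$min_cpgs[cl])
  }
  o <- reg[order(reg$first_row), ]
  expect_true(all(o$first_row[-1] - o$last_row[-nrow(o)] > 10L))

  none <- sample_dmr_regions(bb$probes, sim_config(n_dmrs_per_class = 0),
                             seed = 6)
  expect_equal(nrow(none), 0L)

  # an impossible request names the failing class
  tiny <- generate_backbone(backbone_config(n_probes = 60, n_samples = 2),
                            seed = 7)
  expect_error(sample_dmr_regions(tiny$probes,
                                  sim_config(n_dmrs_per_class = 40), seed = 7),
               "size class")
})

test_that("injection masks interior probes, inflates the higher group and rescales", {
  # explicit worked case: (0.85, 0.95) + 0.2 exceeds 1, whole probe / 1.15
  beta <- matrix(c(0.85, 0.95, 0.10, 0.20), 1,
                 dimnames = list("p1", c("A1", "A2", "B1", "B2")))
  beta <- beta[c(1, 1, 1), ]; rownames(beta) <- paste0("p", 1:3)
  groups <- data.frame(sample_id = c("A1", "A2", "B1", "B2"),
                       group = c("g1", "g1", "g2", "g2"))
  reg <- data.frame(chrom = "chr1", start = 1L, end = 300L,
                    first_row = 1L, last_row = 3L, n_cpgs = 3L,
                    size_class = 1L)
  out <- inject_dmrs(beta, groups, reg,
                     sim_config(noise = 0, delta_beta = 0.2), seed = 1)
  expect_equal(unname(out$beta[1, ]), c(1.05, 1.15, 0.10, 0.20) / 1.15)
  expect_equal(max(out$beta), 1)
  expect_equal(out$regions$inflated_group, "g1")
  expect_equal(out$regions$masked_rows[[1]], integer(0))   # noise 0

  # a 2-probe region has no interior, nothing maskable at any noise
  beta2 <- matrix(runif(8, 0.2, 0.5), 2,
                  dimnames = list(c("p1", "p2"), c("A1", "A2", "B1", "B2")))
  reg2 <- data.frame(chrom = "chr1", start = 1L, end = 200L, first_row = 1L,
                     last_row = 2L, n_cpgs = 2L, size_class = 1L)
  out2 <- inject_dmrs(beta2, groups, reg2,
                      sim_config(noise = 0.9, delta_beta = 0.1), seed = 1)
  expect_equal(out2$regions$masked_rows[[1]], integer(0))
})

test_that("masked probes keep their original beta and values stay in range", {
  sim <- small_sim(seed = 17, n_probes = 6000, per_class = 3)
  bb <- generate_backbone(backbone_config(n_probes = 6000, n_samples = 12),
                          seed = 17)
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  for (i in seq_len(nrow(sim$truth))) {
    masked <- sim$truth$masked_rows[[i]]
    rows <- sim$truth$first_row[i]:sim$truth$last_row[i]
    expect_false(sim$truth$first_row[i] %in% masked)
    expect_false(sim$truth$last_row[i] %in% masked)
    interior <- setdiff(rows, range(rows))
    expect_equal(length(masked), floor(sim$config$noise * length(interior) + 0.5))
    if (length(masked)) {
      expect_equal(sim$beta[masked, , drop = FALSE],
                   bb$beta[masked, , drop = FALSE])
    }
  }
})

test_that("realized beta offset at unmasked injected probes tracks delta_beta", {
  sim <- small_sim(seed = 19, n_probes = 8000, per_class = 4)
  g <- sim$groups
  offs <- unlist(lapply(seq_len(nrow(sim$truth)), function(i) {
    rows <- setdiff(sim$truth$first_row[i]:sim$truth$last_row[i],
                    sim$truth$masked_rows[[i]])
    hi <- g$sample_id[g$group == sim$truth$inflated_group[i]]
    lo <- g$sample_id[g$group != sim$truth$inflated_group[i]]
    rowMeans(sim$beta[rows, hi, drop = FALSE]) -
      rowMeans(sim$beta[rows, lo, drop = FALSE])
  }))
  # mean realized offset approximates the parameter, allowing rescaling loss
  # and the backbone's own group-mean noise
  expect_gt(mean(offs), sim$config$delta_beta * 0.6)
  expect_lt(mean(offs), sim$config$delta_beta * 1.2)
})

test_that("full simulation composes reproducibly and writes truth artifacts", {
  s1 <- small_sim(seed = 23, n_probes = 3000)
  s2 <- small_sim(seed = 23, n_probes = 3000)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$truth$start, s2$truth$start)
  expect_equal(nrow(s1$truth), 4 * 2)     # classes x per-class

  dir <- tempfile()
  write_simulation(s1, dir)
  bed <- read_bed(file.path(dir, "truth.bed"))
  expect_equal(nrow(bed), nrow(s1$truth))
  expect_equal(sort(bed$start), sort(s1$truth$start))
  par <- jsonlite::read_json(file.path(dir, "simulation.json"))
  expect_equal(par$noise, s1$config$noise)
  expect_equal(par$seed, 23L)
})
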