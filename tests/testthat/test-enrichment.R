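# independent two-sided Fisher p for a 2x2 table by enumerating the
# hypergeometric support and summing probabilities <= the observed one
enum_fisher_p <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(k, m)
  d <- dhyper(supp, m, n, k)
  sum(d[d <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("probe membership respects inclusive boundaries", {
  ps <- probe_set(paste0("p", 1:5), rep("chr1", 5),
                  c(50L, 100L, 150L, 151L, 200L))
  reg <- region_df("chr1", 100L, 150L)
  expect_equal(cpg_membership(ps, reg), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(cpg_membership(ps, reg[0, ]), rep(FALSE, 5))
  expect_error(cpg_membership(ps, region_df("chr1", c(100L, 120L),
                                            c(150L, 160L))),
               "non-overlapping")
})

test_that("odds ratios come from the exact conditional test with exact CI", {
  a <- rep(c(TRUE, FALSE), c(20, 30)); a <- c(a, rep(c(TRUE, FALSE), c(5, 45)))
  set.seed(1)
  # construct memberships giving table (20,5;5,20)
  m_a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 5, 5, 20))
  m_b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 5, 20))
  r <- fisher_or(m_a, m_b)
  expect_equal(unname(r$table[1, ]), c(20L, 5L))
  expect_equal(r$or_sample, 16)
  expect_equal(r$p, enum_fisher_p(r$table), tolerance = 1e-9)
  expect_true(r$ci_low <= r$or && r$or <= r$ci_high)

  # independence: sample OR 1, p near 1
  m1 <- rep(c(TRUE, FALSE), 20)
  m2 <- rep(c(TRUE, TRUE, FALSE, FALSE), 10)
  ind <- fisher_or(m1, m2)
  expect_equal(ind$or_sample, 1)
  expect_gt(ind$p, 0.5)

  # zero diagonal cell: OR estimate 0 with finite p
  m3 <- rep(c(TRUE, FALSE), c(50, 50))
  z <- fisher_or(m3, !m3)
  expect_equal(z$or, 0)
  expect_lt(z$p, 1e-10)

  # universe mask restricts the table
  u <- rep(c(TRUE, FALSE), c(50, 50))
  r2 <- fisher_or(m_a, m_b, universe = u)
  expect_equal(sum(r2$table), 50)
})

test_that("fisher_or is symmetric under swapping the annotations", {
  set.seed(8)
  x <- runif(300) < 0.3; y <- runif(300) < 0.4
  r1 <- fisher_or(x, y); r2 <- fisher_or(y, x)
  expect_equal(r1$or, r2$or)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$table, t(r2$table), ignore_attr = TRUE)
})

test_that("independent memberships give calibrated two-sided p-values", {
  set.seed(9)
  ps <- replicate(300, fisher_or(runif(120) < 0.4, runif(120) < 0.4)$p)
  # discrete exact p-values are super-uniform
  for (a in c(0.1, 0.3)) expect_lte(mean(ps <= a), a + 3 * sqrt(a / 300))
  expect_gt(mean(ps <= 0.5), 0.2)
})

test_that("gaps between regions partition the span with the regions", {
  span <- region_df("chrX", 1L, 60L)
  layer <- region_df("chrX", c(10L, 40L), c(20L, 50L))
  g <- layer_gap_regions(layer, span)
  expect_equal(g$start, c(1L, 21L, 51L))
  expect_equal(g$end, c(9L, 39L, 60L))
  # exact partition: widths add to the span, no overlap
  expect_equal(sum(g$end - g$start + 1) + sum(layer$end - layer$start + 1),
               span$end - span$start + 1)

  full <- layer_gap_regions(region_df("chrX", 1L, 60L), span)
  expect_equal(nrow(full), 0L)          # whole span consolidated: no gaps
  none <- layer_gap_regions(layer[0, ], span)
  expect_equal(none$start, 1L)
  expect_equal(none$end, 60L)
})

test_that("cross-condition overlap counts regions and genes separately", {
  a <- region_df("chr1", c(100L, 500L), c(200L, 600L))
  same <- condition_overlap(a, a)
  expect_equal(same$frac_a_overlapped, 1)
  expect_equal(same$frac_b_overlapped, 1)

  disjoint <- condition_overlap(a, region_df("chr1", 1000L, 1100L))
  expect_equal(disjoint$n_pairs, 0L)
  expect_equal(disjoint$frac_a_overlapped, 0)

  # shared gene reached through non-overlapping parts of the gene body
  genes <- region_df("chr1", 100L, 1000L, name = "GENE1")
  b <- region_df("chr1", 800L, 900L)
  res <- condition_overlap(a, b, genes)
  expect_equal(res$n_pairs, 0L)                 # regions do not overlap
  expect_equal(res$genes_shared, "GENE1")       # but the gene is shared
  expect_equal(res$frac_genes_a_shared, 1)
})

test_that("layer gaps in a consolidated fit expose unenriched islands", {
  # chromosome-wide signal with a silent island, over a null background
  # chromosome that anchors the rank scale (as autosomes do for chrX)
  set.seed(51)
  n <- 300
  chr1 <- toy_probes(n)
  chr2 <- toy_probes(3000, chrom = "chr2")
  all_ps <- probe_set(c(chr1$probe_id, chr2$probe_id),
                      c(chr1$chrom, chr2$chrom), c(chr1$pos, chr2$pos))
  p <- c(1e-8 * runif(n), runif(3000, 0.3, 1))
  p[140:160] <- runif(21, 0.5, 1)
  fit <- dmrscale(probes = all_ps, test = "precomputed",
                  track = toy_track(all_ps, p),
                  config = dmr_config(windows = c(4, 8), locs_cutoff = 0.01))
  top <- as.data.frame(fit)
  ps <- all_ps[all_ps$chrom == "chr1", ]
  span <- region_df("chr1", min(ps$pos), max(ps$pos))
  gaps <- layer_gap_regions(top[top$chrom == "chr1", ], span)
  member_gap <- cpg_membership(ps, gaps)
  expect_true(all(which(member_gap) >= 140 & which(member_gap) <= 160))
  escape <- seq_len(n) %in% 140:160
  r <- fisher_or(member_gap, escape)
  expect_gt(r$or, 10)
  expect_lt(r$p, 1e-6)
})
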