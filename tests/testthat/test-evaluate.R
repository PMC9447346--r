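test_that("width pairing forms one pair per overlapping combination", {
  truth <- region_df("chr1", c(1000L, 5000L), c(1999L, 6999L))
  exact <- pair_widths(truth, truth)
  expect_equal(nrow(exact$pairs), 2L)
  expect_equal(exact$r_log10, 1)
  expect_equal(exact$r_raw, 1)

  none <- pair_widths(truth, region_df("chr1", 9000L, 9500L))
  expect_equal(nrow(none$pairs), 0L)
  expect_true(is.na(none$r_log10))

  # 1 kb truth overlapped by two 0.5 kb calls: two pairs
  two <- pair_widths(region_df("chr1", 1000L, 1999L),
                     region_df("chr1", c(1000L, 1500L), c(1499L, 1999L)))
  expect_equal(nrow(two$pairs), 2L)
  expect_true(is.na(two$r_log10))   # zero variance in widths
})

test_that("mapping values flag fragmentation and agglomeration", {
  # clean one-to-one
  t1 <- region_df("chr1", 100L, 200L)
  m1 <- mapping_values(t1, t1)
  expect_equal(unname(m1$values), 1)
  expect_equal(m1$one_to_one, 1)

  # one called region spanning two truths: both get 1/2
  t2 <- region_df("chr1", c(100L, 300L), c(200L, 400L))
  m2 <- mapping_values(t2, region_df("chr1", 50L, 450L))
  expect_equal(unname(m2$values), c(0.5, 0.5))
  expect_equal(m2$one_to_one, 0)

  # one truth fragmented across three exclusive calls: value 3
  t3 <- region_df("chr1", 100L, 400L)
  m3 <- mapping_values(t3, region_df("chr1", c(100L, 200L, 300L),
                                     c(150L, 250L, 350L)))
  expect_equal(unname(m3$values), 3)

  # unmatched truths count in the one-to-one denominator
  t4 <- region_df("chr1", c(100L, 900L), c(200L, 950L))
  m4 <- mapping_values(t4, region_df("chr1", 100L, 200L))
  expect_equal(m4$one_to_one, 0.5)
  expect_equal(m4$n_unmatched, 1L)
})

test_that("feature precision-recall weights every truth region equally", {
  truth <- region_df("chr1", c(1000L, 5000L), c(1999L, 5999L))
  # one perfect call out of two truths: precision 1, recall 1/2 at step 1
  one <- region_df("chr1", 1000L, 1999L, p = 1e-5)
  pr <- feature_pr_curve(truth, one)
  expect_equal(pr$curve$precision, 1)
  expect_equal(pr$curve$recall, 0.5)

  # call inside the truth covering half of it
  half <- feature_pr_curve(region_df("chr1", 1000L, 1999L),
                           region_df("chr1", 1000L, 1499L, p = 1e-5))
  expect_equal(half$curve$precision, 1)
  expect_equal(half$curve$recall, 0.5)

  # perfect two-call set: AUCPR 1
  both <- truth; both$p <- c(1e-8, 1e-6)
  pr2 <- feature_pr_curve(truth, both)
  expect_equal(pr2$aucpr, 1)
  expect_true(all(diff(pr2$curve$recall) >= 0))

  expect_equal(feature_pr_curve(truth, truth[0, ])$aucpr, 0)
})

test_that("recall is monotone along random inclusion orders", {
  set.seed(41)
  for (i in 1:5) {
    truth <- region_df("chr1", s <- sort(sample.int(99000, 6)) * 10L,
                       s * 10L + sample(500:5000, 6))
    cs <- sort(sample.int(990000, 10))
    called <- region_df("chr1", cs, cs + sample(200:8000, 10))
    called$p <- runif(10)
    pr <- feature_pr_curve(truth, called)
    expect_true(all(diff(pr$curve$recall) >= -1e-12))
  }
})

test_that("confusion metrics recover closed-form values from direct counts", {
  ps <- toy_probes(100, spacing = 1L)     # unit spacing: cpg == bp counts
  truth <- region_df("chr1", 1L, 10L)
  called <- region_df("chr1", 3L, 12L)
  for (lev in c("bp", "cpg")) {
    m <- confusion_metrics(truth, called, lev, probes = ps)
    expect_equal(unname(m$counts), c(8, 2, 2, 88))
    expect_equal(m$precision, 0.8)
    expect_equal(m$recall, 0.8)
    expect_equal(m$fdr, 0.2)
    expect_equal(m$f1, 0.8)
    expect_equal(m$mcc, (8 * 88 - 2 * 2) / sqrt(10 * 10 * 90 * 90))
  }
})

test_that("a perfect caller attains ideal values at every level", {
  ps <- toy_probes(200, spacing = 50L)
  truth <- region_df("chr1", c(500L, 3000L), c(1000L, 4000L))
  called <- truth; called$p <- c(1e-9, 1e-7)
  for (lev in c("feature", "bp", "cpg")) {
    m <- confusion_metrics(truth, called, lev, probes = ps)
    expect_equal(m$precision, 1)
    expect_equal(m$recall, 1)
    expect_equal(m$specificity, 1)
    expect_equal(m$f1, 1)
    expect_equal(m$mcc, 1)
    expect_equal(m$fdr, 0)
  }
  expect_equal(feature_pr_curve(truth, called)$aucpr, 1)
})

test_that("calling the whole domain maximizes recall and zeroes specificity", {
  ps <- toy_probes(100, spacing = 10L)
  truth <- region_df("chr1", 100L, 300L)
  whole <- region_df("chr1", 10L, 1000L, p = 1e-3)
  m <- confusion_metrics(truth, whole, "bp", probes = ps)
  expect_equal(m$recall, 1)
  expect_equal(m$specificity, 0)
})

test_that("a random caller on a null domain has MCC near zero", {
  set.seed(42)
  ps <- toy_probes(2000, spacing = 10L)
  truth_starts <- sort(sample.int(1900, 20)) * 10L
  truth <- region_df("chr1", truth_starts, truth_starts + 90L)
  mccs <- replicate(20, {
    cs <- sort(sample.int(1900, 20)) * 10L
    called <- region_df("chr1", cs, cs + 90L)
    confusion_metrics(truth, called, "cpg", probes = ps)$mcc
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("legacy printed formula variants are reported behind the flag", {
  ps <- toy_probes(100, spacing = 1L)
  m <- confusion_metrics(region_df("chr1", 1L, 10L),
                         region_df("chr1", 3L, 12L), "bp", probes = ps,
                         legacy = TRUE)
  expect_true(is.finite(m$specificity_legacy))
  expect_true(is.finite(m$mcc_legacy))
})

test_that("the evaluation wrapper aggregates all levels", {
  sim <- small_sim(seed = 29, n_probes = 3000)
  truth <- sim$truth
  called <- truth[, c("chrom", "start", "end")]
  called$p <- runif(nrow(called))
  ev <- evaluate_calls(truth, called, sim$probes)
  expect_equal(ev$metrics$feature$precision, 1)
  expect_equal(ev$mapping$one_to_one, 1)
  expect_equal(ev$pr$aucpr, 1)
})
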