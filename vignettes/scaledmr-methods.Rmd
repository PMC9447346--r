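---
title: "Scale-aware DMR calling: model, simulator and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-aware DMR calling: model, simulator and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaledmr)
```

## The problem

Differential DNA methylation between two groups of samples organizes itself
at wildly different genomic scales: a few CpGs at a promoter, tens of
kilobases over a gene cluster, or — in the extreme case of X inactivation —
an entire chromosome. Methods tuned to one scale fragment large features or
drown small ones. `scaledmr` scans the genome with windows defined by counts
of *adjacent measured CpGs* (so the scan is agnostic to CpG density), scores
each window with a sequential hypergeometric rank-enrichment statistic, and
repeats the scan at increasing window sizes, integrating the results into a
nested hierarchy of region layers.

The input is deliberately minimal: a normalized beta-value matrix (probes
times samples, values in [0, 1]), a probe manifest with genomic coordinates,
and a two-group sample sheet — or, instead of the matrix, a precomputed
per-CpG p-value track from any model the analyst prefers. Array
preprocessing (idat parsing, background correction, normalization) is out
of scope; the package consumes its output.

## Per-CpG significance and ranks

`cpg_wilcoxon()` tests each probe with the two-sided Wilcoxon rank-sum test,
exact (via the `pwilcox` distribution) when the smaller group has at most 10
samples and the probe has no tied values, otherwise normally approximated
with continuity and tie correction. `cpg_ttest()` provides Welch's t as an
alternative; `precomputed_track()` accepts external p-values.

Each probe then receives a significance rank
\[K_i = \#\{j : p_j \le p_i\},\]
so rank 1 is the uniquely most significant probe and tied p-values share the
maximal count. This direction is forced by the window score below, where the
rank doubles as the number of "success cases" in a hypergeometric draw:
the bookkeeping is only self-consistent if the rank counts probes at least
as significant.

The individual-CpG p-value cutoff that separates "significant" probes can
be given directly or estimated by `permutation_fdr_cutoff()`: the per-CpG
tests are repeated under random permutations of the group labels, and for
each candidate cutoff c the false discovery proportion is estimated as the
mean permuted exceedance count over the observed exceedance count,
monotonized by a running maximum before thresholding. How the permuted and observed distributions are turned into one concrete
cutoff is a genuinely open design point; the estimator here is one
defensible choice and is flagged as such.
Because a label permutation leaves within-probe ranks untouched, the
permutation replicates reuse the observed rank matrix and cost almost
nothing.

## The window score

For a window, consider the ranks of its individually-significant member
CpGs. The most significant member (smallest rank, ties broken by the
leftmost position) is taken as given — the conditioning draw — and the
remaining m members, ordered from least to most significant, contribute
\[p_{region} = \prod_{i=1}^{m} P(X_i \ge k_i), \qquad
  X_i \sim \mathrm{Hypergeometric}(N_i, K_i, n_i),\]
with \(K_i\) the i-th member's rank, \(k_i\) the number of members ranked at
least as significant, \(n_1 = m\), \(n_i = k_{i-1} - 1\),
\(N_1 = N\) (the track size), and \(N_i = K_{i-1} - 1\). Each factor asks:
given that everything more extreme than the previous member has been
conditioned away, how surprising is it that the remaining draws all fall
within the top \(K_i\) ranks? A single-member region is the empty product,
1: one significant CpG alone never makes a region.

Two design points deserve emphasis:

* **Only significant members are draws.** The statistic measures whether
  individually-significant CpGs associate by adjacency. Members above the
  individual-CpG cutoff carry no rank information worth conditioning on; if
  instead every window member entered the product, the statistic would be a
  Fisher-style product of order-statistic probabilities whose null
  distribution collapses toward 0 as the window grows (we measured
  empirical null \(P(p_{region} \le 10^{-4})\) near 0.04 for windows of 8
  and near 1 for windows of 16 under that reading), making every large
  window "significant". With significant-member draws the pipeline's null
  behaviour is super-uniform, which the acceptance suite verifies directly.
* **Ties are expanded, not guessed.** Tied max-count ranks inside a window
  would make the population updates inconsistent (\(K_i > N_i\)). A group
  of t members sharing rank K occupies the distinct positions
  \(K-t+1, \dots, K\), assigned leftmost-first; `score_region()` works on
  these effective ranks, which reduces each factor to the all-successes
  hypergeometric tail and agrees exactly with the direct formula whenever
  ranks are distinct.

All accumulation is in natural-log space via the stable survival function;
the linear-scale `p_region` is floored at the smallest positive double and a
`log10_p_region` field preserves the true magnitude (chromosome-scale
regions can reach \(10^{-2000}\)).

## Scan, correction, merge, integrate

Windows of w adjacent probes are laid at stride 1 within each chromosome
(windows never cross chromosomes; stride 1 maximizes sensitivity and there
are nearly as many windows as probes). Windows containing no
sub-cutoff probe are not candidates. Candidate scores are corrected with
either Bonferroni or Benjamini–Yekutieli, taking the number of tests to be
the number of probes below the individual-CpG cutoff — not the number of
windows — and windows with adjusted p below `region_cutoff` (default 0.01)
are retained. `stats::p.adjust(n = n_tests)` supplies exactly the step-up
with p = 1 placeholders this requires. Correction is applied independently
within each layer; layers share the same per-CpG evidence base, so no
cross-layer correction is attempted.

Selected windows that overlap or abut in probe-index space are unioned and
the merged region rescored, so the merged unit carries a comparable score
into integration. A region's genomic extent runs from its first to its last
member CpG.

From the second window size onward, `integrate_layers()` reconciles the new
tentative regions with the previous layer: every overlapping previous-layer
region is removed from the candidate in turn and the remainder rescored.
The candidate survives only if *every* remainder remains significant under
the layer's adjusted rule (the retest uses the conservative rank-1 form of
the same correction; an empty remainder fails). Survivors absorb their
overlapping previous regions; otherwise the previous regions stand, and
previous regions without any overlapping candidate are carried through.
Regions are therefore added, expanded or consolidated across layers but
never lost, every lower-layer region nests inside exactly one upper-layer
region, and broad regions appear only when no single smaller region
explains their significance.

`dmrscale()` wires these steps into a single fitting call returning a
classed object with `print`, `summary`, `plot` and `as.data.frame` methods —
the classic modelling-function shape, which fits a caller whose result is a
fitted hierarchy; per-observation methods (`predict`, `residuals`) have no
meaning here and are deliberately absent. The top layer is the primary
output; `write_dmrscale()` exports every layer as BED + TSV with a hierarchy
edge list and JSON run metadata.

## The simulator

`simulate_methylation()` reproduces the DMR-injection benchmark design.
A synthetic backbone stands in for a real array foundation so every module
is testable offline:

* **Probe layout** mixes island-like short gaps (Poisson around 150 bp,
  70 % of gaps) with sparse background gaps (exponential, mean 9 kb) over
  four chromosomes — clustered-plus-sparse spacing like a methylation
  array's.
* **Beta values** draw per-probe baselines from a bimodal Beta mixture
  (modes near 0.06 and 0.94, a 10 % intermediate component) and scatter
  samples around the baseline with standard deviation
  `dispersion * sqrt(b(1-b))` (default dispersion 0.15, about 0.02–0.04
  s.d. for extreme baselines), clipped to [0, 1].

Ground-truth regions are drawn log-uniformly within four decade size
classes — 0.1–1 kb, 1–10 kb, 10–100 kb and 0.1–1 Mb, requiring at least
3, 6, 9 and 12 member CpGs respectively — snapped to probe spans,
non-overlapping, and at least 10 probes from each other. Injection masks a
`noise` fraction of each region's interior CpGs (never the first or last;
count rounded half-up), adds `delta_beta` to every non-masked member CpG of
whichever group has the higher regional mean, and, where any sample exceeds
1, divides *all* samples' values at that probe by the probe maximum — which
slightly shrinks the uninflated group too; this is the deliberate reading
of the rescale rule. Defaults (8 per group, 25 regions per class,
noise 0.5, delta-beta 0.2) are the central benchmark condition.

What the backbone does **not** emulate: spatial correlation of methylation
between neighbouring CpGs, batch structure, SNP-probe artifacts, and
cell-composition effects. Passing benchmarks on this backbone therefore
demonstrate the statistical machinery, not robustness to those real-data
phenomena; the same pipeline accepts a real beta matrix as its backbone
unchanged.

## Evaluation statistics

`evaluate_calls()` benchmarks any caller's regions against truth:

* **Width pairs** (any-overlap pairing) with Pearson correlation on log10
  widths — the scale on which the size classes are laid out — and on raw
  widths.
* **Mapping values** per truth region: the number of called regions
  overlapping it (fragmentation) or the inverse of the largest number of
  truth regions sharing one of its called regions (agglomeration),
  whichever is farther from 1 in log; exactly 1 is clean one-to-one
  recovery. Unmatched truth regions are excluded from the distribution but
  count in the one-to-one denominator.
* **Feature-level precision–recall** by stepwise inclusion of called
  regions in significance order: precision is the mean covered fraction of
  included called regions; recall is the mean truth-region coverage by
  their union, giving every truth region equal weight regardless of size.
  AUCPR integrates the curve over recall with a prepended
  (0, first-precision) point. The false-negative term for a truth region is the complement of its
  coverage — the only definition keeping recall in [0, 1].
* **Confusion metrics** at basepair and CpG resolution from direct counts,
  with textbook specificity TN/(TN+FP) and MCC from the 2×2 counts. At
  feature level the fractional TP/FP/FN masses are completed with a
  true-negative count of truth-free domain gaps untouched by any call, so
  specificity and MCC are defined and a perfect caller attains 1
  everywhere. Some DMR benchmarking studies report specificity and MCC through
  non-standard single-ratio formulas; those variants are reproduced behind
  `legacy = TRUE` for comparison only.

## Enrichment analyses

`cpg_membership()`, `fisher_or()`, `layer_gap_regions()` and
`condition_overlap()` support the membership contingency analyses: odds
ratios between CpGs in DMR gaps and annotation intervals (the X-inactivation
escape analysis — at the top layer a fully consolidated chromosome has no
gaps, and the enrichment vanishes by construction), and cross-condition
region/gene overlap, where a gene can be shared through non-overlapping
parts of its body even when no regions intersect. Odds ratios are the
conditional maximum-likelihood estimates with exact 95 % intervals from
`stats::fisher.test` (the convention that yields very wide intervals for
sparse tables), with the raw cross-ratio reported alongside.

## Numerical and testing choices

* Probability accumulation in log space throughout; `p_region` floored at
  `.Machine$double.xmin`; BED scores are capped at 1000.
* Internal coordinates are 1-based inclusive; BED is emitted and read as
  0-based half-open.
* Duplicate probe positions are collapsed to one probe with a warning (the
  platform-overlap case the manifests leave ambiguous).
* Every stochastic step takes an explicit seed and is reproducible
  bit-for-bit; the fit is deterministic given inputs and configuration.
* The test suite verifies the window score against an independent
  exact-rational oracle (enumerated hypergeometric tails) exhaustively over
  every rank subset of up to 6 members for track sizes up to 16 and on
  randomized draws up to size 30, at 1e-12 relative tolerance; null
  calibration on ~15,000 random-rank windows of 8; the nesting invariant on
  100 randomized end-to-end runs; and a scaled parameter-recovery benchmark
  on a 50,000-probe backbone with 25 injected regions per size class
  (8 vs 8, delta-beta 0.2, noise 0.5, windows 4–64, BY 0.01) — sizes chosen
  so the whole suite runs on a laptop in a couple of minutes.

## Known limitations

* **Consolidation at high truth density.** The integration step keeps a
  broad region whenever no single smaller region explains it, so two strong
  regions closer than roughly the largest window (in probe index space) are
  merged at the top layer by design — the behaviour that consolidates a
  whole chromosome when the signal is chromosome-wide. On dense benchmarks
  where many injected regions sit within ~64 probes of each other, top-layer
  one-to-one recovery and width correlation degrade for exactly this
  reason; the middle layers retain the separated representation, and the
  hierarchy keeps both views.
* The permutation cutoff inherits the discreteness of the exact rank-sum
  test at small group sizes; with 8 vs 8 samples no p-value below
  2/C(16,8) is achievable, and probes tied at that floor share one rank.
* No covariate adjustment; supply a precomputed p-value track from a
  covariate-aware model instead.
* Fixed genomic-width windows are not offered; windows are CpG counts.
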