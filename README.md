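# scaledmr

Scale-aware calling of differentially methylated regions (DMRs) from
methylation-array beta values.

Differential DNA methylation lives at every genomic scale: a handful of CpGs
at a promoter, tens of kilobases across a gene cluster, megabases of
heterochromatin, or — between XX and XY blood — essentially the whole
X chromosome. Callers built around a single bandwidth either fragment the
large features or blur away the small ones. `scaledmr` is for analysts with
a normalized beta matrix (450K/EPIC-style array data, or anything
probe-shaped) who want one analysis that recovers features across that
entire range and reports how small regions nest inside large ones.

## The statistic

Windows are defined by counts of adjacent measured CpGs (density-agnostic),
slid at stride 1 within each chromosome. Each probe carries a significance
rank *K<sub>i</sub>* = #{j : p<sub>j</sub> ≤ p<sub>i</sub>} from a two-group
test (exact Wilcoxon rank-sum by default; Welch t or precomputed p-values as
alternatives). A window's individually-significant members, after excluding
its most significant CpG as the conditioning draw and ordering the remaining
m from least to most significant, score

> p<sub>region</sub> = ∏<sub>i=1..m</sub> P(X<sub>i</sub> ≥ k<sub>i</sub>),  X<sub>i</sub> ~ Hypergeometric(N<sub>i</sub>, K<sub>i</sub>, n<sub>i</sub>)

with n<sub>1</sub> = m, n<sub>i</sub> = k<sub>i−1</sub> − 1, N<sub>1</sub> = N,
N<sub>i</sub> = K<sub>i−1</sub> − 1: each factor asks how surprising it is
that the remaining draws all fall within the top K<sub>i</sub> ranks, after
conditioning away everything more extreme. Window scores are corrected
(Benjamini–Yekutieli or Bonferroni, with the test count equal to the number
of probes below the individual-CpG cutoff), significant windows are merged,
and the scan repeats at increasing window sizes (default 4, 8, 16, 32, 64
adjacent CpGs). A subtract-and-retest integration step keeps a broader
region only when no single smaller region explains its significance, so the
layers form a nested hierarchy in which regions are added, expanded or
consolidated but never lost.

The package also ships the benchmark machinery around the caller: a
DMR-injection simulator over a synthetic array-like backbone (bimodal beta
values, clustered + sparse probe spacing, size-class constraints, interior
noise masking, delta-beta inflation with max-rescaling), range-aware
feature/basepair/CpG-level evaluation (precision–recall curves, AUCPR, F1,
MCC, width correlation, one-to-one mapping values), and CpG-membership
enrichment analyses (Fisher odds ratios, DMR-gap extraction,
cross-condition region/gene overlap).

## Worked example

Simulate a 20,000-probe dataset with 40 injected DMRs spanning 0.1 kb–1 Mb
(8 vs 8 samples, delta-beta 0.2, half the interior CpGs masked), call
regions, and benchmark the top layer against the injected truth:

```r
library(scaledmr)

sim <- simulate_methylation(backbone_config(n_probes = 20000, n_samples = 20),
                            sim_config(n_dmrs_per_class = 10), seed = 42)
fit <- dmrscale(sim$beta, sim$probes, sim$groups, config = dmr_config(seed = 42))
print(fit)
#> Scale-aware DMR fit
#>   probes: 20000 on 4 chromosome(s)
#>   individual-CpG cutoff: 0.004662 (793 probes below; BY correction, region cutoff 0.01)
#>   layer 1 ( 4 adj. CpGs):   43 region(s), 450,782 bp covered
#>   layer 2 ( 8 adj. CpGs):   49 region(s), 2,760,991 bp covered
#>   layer 3 (16 adj. CpGs):   31 region(s), 3,365,619 bp covered
#>   layer 4 (32 adj. CpGs):   31 region(s), 3,365,619 bp covered
#>   layer 5 (64 adj. CpGs):   30 region(s), 3,593,786 bp covered

called <- as.data.frame(fit)          # top layer = primary output
called$p <- called$log10_p_region
ev <- evaluate_calls(sim$truth, called, sim$probes)
cat(sprintf("log10-width r = %.2f | one-to-one = %.2f | feature precision = %.2f | AUCPR = %.2f\n",
    ev$widths$r_log10, ev$mapping$one_to_one,
    ev$metrics$feature$precision, ev$pr$aucpr))
#> log10-width r = 0.93 | one-to-one = 0.70 | feature precision = 0.94 | AUCPR = 0.68
```

Reading the fit: the permutation step chose the individual-CpG p-value
cutoff reaching FDR < 0.10 (here 0.0047, 793 probes below it); layer 1
resolves the small features, and successive layers consolidate them — the
coverage growth from 0.45 Mb to 3.6 Mb is the large size classes being
assembled from their fragments. In the benchmark line, the width
correlation (Pearson r on log10 widths of overlapping truth/called pairs)
says called widths track true widths across four orders of magnitude;
one-to-one is the fraction of injected regions recovered as exactly one
called region; feature precision is the mean fraction of each called
region's span lying on true regions. The strongest calls are the megabase-scale
regions, e.g.:

```r
head(called[order(called$log10_p_region),
            c("chrom", "start", "end", "n_cpgs", "log10_p_region", "p_adjusted")], 3)
#>    chrom    start      end n_cpgs log10_p_region    p_adjusted
#> 20  chr3 10129512 10777906    251     -195.03324 5.328329e-192
#> 4   chr1  8948764  9700975    283     -161.45479 1.009290e-158
#> 30  chr4  9648948 10122774    161     -124.24517 1.090275e-121
```

`write_dmrscale(fit, "out/")` exports every layer as BED + TSV with a
hierarchy edge list and run metadata; `plot(fit)` draws the layer tracks.
The same steps are available from the shell via `exec/scaledmr`
(`simulate`, `call`, `evaluate`, `enrich`, `overlap` subcommands).

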