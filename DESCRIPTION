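Package: scaledmr
Title: Scale-Aware Calling of Differentially Methylated Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from normalized
    methylation-array beta values across the full range of genomic scale, from
    sub-kilobase promoter features to whole-chromosome differential
    methylation. Windows are defined by counts of adjacent CpG probes and
    scored with a sequential hypergeometric rank-enrichment statistic; scans
    at increasing window sizes are integrated into a nested hierarchy of
    region layers with region-level Benjamini-Yekutieli or Bonferroni
    control. Includes a DMR-injection simulator with an array-like synthetic
    backbone, range-aware feature/basepair/CpG-level benchmarking statistics
    (precision-recall curves, AUCPR, F1, MCC), and CpG-membership enrichment
    analyses (Fisher odds ratios, DMR-gap analysis, cross-condition overlap).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
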