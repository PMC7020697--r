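Package: medipdmr
Title: Differential Methylation Analysis for MeDIP Promoter Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for methylated-DNA immunoprecipitation (MeDIP) promoter
    tiling-array analysis: per-sample normalization of log2 MeDIP/Input
    ratios, sliding-window enrichment peak calling, the M' per-probe
    differential statistic with two-criterion filtering of differential
    enrichment peaks (DEPs), CpG-density promoter classification
    (HCP/ICP/LCP), promoter annotation and hypergeometric gene-set
    over-representation with Benjamini-Hochberg adjustment, plus the
    validation-layer statistics used alongside such arrays: bisulfite-clone
    methylation ratios, qPCR relative expression (delta-delta-Ct), oral
    glucose tolerance test AUC and HOMA-IR. A seeded synthetic-data
    generator emulates the array, promoter sequences, bisulfite clone
    matrices and phenotype tables with planted ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
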