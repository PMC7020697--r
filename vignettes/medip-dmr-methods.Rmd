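---
title: "Methods: MeDIP promoter-array differential methylation in medipdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MeDIP promoter-array differential methylation in medipdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

## Scope and data model

`medipdmr` analyses two-channel MeDIP-chip promoter tiling arrays: each
probe carries one log2(MeDIP/Input) ratio per biological replicate, and the
design contrasts exactly two groups (by default labelled `HF-inulin` vs
`HF`, a maternal dietary intervention against its high-fat control, with
three replicates each). All genomic intervals are 0-based half-open
throughout — in the probe table, in peaks, and in BED files on disk — so no
coordinate convention changes between modules. Probe tables are kept sorted
by (chromosome, start) and validated on construction.

## Normalization

Array-level normalization upstream of this package (dye and spatial
effects) is out of scope; `normalize_log2_ratios()` performs the one step
the downstream statistics assume, median-centering each sample so that the
"enriched vs array background" comparison is anchored at zero. Median
centering is robust to the minority of enriched probes and preserves scale,
which matters because the DEP filter applies an absolute 0.3 log2
threshold.

## Probe scores and peak calling

Commercial peak callers for this platform score each probe by comparing a
small window of surrounding probes against the array-wide distribution.
`score_probes()` implements that idea as a one-sided Mann–Whitney rank-sum
test: for probe *i*, the values of all probes whose midpoints lie within
±375 bp (a 750-bp centered window) are compared against the distribution of
all probes, alternative "greater", and the score is −log10 of the normal
approximation with tie and continuity correction. The implementation is a
rolling rank-sum — one global ranking plus cumulative sums per chromosome —
and is numerically identical to `stats::wilcox.test()` probe by probe (a
test asserts this), while scaling linearly in array size. A windowed
Kolmogorov–Smirnov alternative is available via
`peak_call_params(test = "ks")`. Windows holding fewer than
`min_occupancy = 4` probes score 0 rather than yielding an unstable
small-sample p-value.

Peaks are maximal runs of probes scoring at or above the cutoff
(−log10 p ≥ 2; the tie goes to inclusion, a reproducible rule), with
consecutive member probes at most 500 bp apart — measured midpoint to
midpoint, since the platform convention names "spacing between probes"
without an anchor — and at least 2 members. A brute-force run enumerator
serves as the test oracle for this segmentation.

Two properties of the windowed score are worth knowing. First, under the
null about 1% of probes exceed the cutoff by construction, but neighbouring
windows share most of their members, so above-cutoff probes arrive in
correlated runs rather than independently. Second, probes at the edge of a
true enriched block have windows diluted with background probes and can
fall below the cutoff even when the block itself is unmissable; peak spans
therefore concentrate on the well-supported interior.

## The differential statistic and DEP filtering

For a treatment/control contrast, `compute_m_prime()` gives each probe
`M' = mean(treatment log2 ratios) − mean(control log2 ratios)`, so the
statistic is antisymmetric in the group labels. Candidate differential
enrichment peaks are found by running the same score-and-segment procedure
on the `M'` track (hypermethylation) and on `−M'` (hypomethylation); a
probe with fewer than two non-missing replicates in either group is
excluded from membership.

Candidates pass `filter_deps()` when

1. at least one group's median log2(MeDIP/Input) over member probes
   reaches 0.3 **and** the median `M'` over member probes is positive in
   the peak's own direction — the direction-aware reading is forced by the
   existence of hypomethylated DEPs, for which `M' < 0` by definition; and
2. in both groups at least half the member probes have a replicate CV of
   at most 0.8, computed on the linear ratio scale `2^x` (a CV of signed
   log-scale values is ill-defined).

All medians are taken over member probes only, and every summary quantity
plus both verdicts are stored on the returned object, so the decision is
reproducible from the output alone. `medip_dmr()` wraps the whole chain and
returns a classed fit with `print`, `summary`, `plot` and `as.data.frame`
methods; swapping treatment and control exchanges the hyper and hypo DEP
sets exactly (a test asserts bit-identical intervals).

## CpG-density promoter classification

Promoters are classified from sequence with the standard windowed
CpG-island criteria: sliding 500-bp windows (step 5 bp) score GC fraction
and the CpG observed/expected ratio `(#CpG · L)/(#C · #G)`, defined as 0
when a window lacks C or G entirely. HCP requires some window with ratio
> 0.75 and GC > 0.55; LCP requires that no window exceed 0.48; everything
else is ICP. The numeric thresholds follow the published classification
scheme the field uses for this three-band split and are exposed through
`cpg_class_thresholds()`. The classification applies to the host promoter
of a DMR, matching the promoter-centric design of the array. The default
promoter window is \[−1300, +500) around the TSS, strand-aware — a typical
commercial promoter-array span; the exact vendor window is not published,
so it is configurable.

## Annotation and over-representation

DEPs map to promoters by ≥ 1 bp interval overlap (half-open, via
GenomicRanges); a DEP spanning two divergent promoters is assigned both
genes, and gene lists are deduplicated, which is why the annotated-gene
count can fall below the DMR count. The enrichment universe is the set of
genes on the array, the standard over-representation choice for array
designs, not the whole genome. Over-representation uses the plain
hypergeometric upper tail (`stats::phyper`) with an in-package
Benjamini–Hochberg step-up (`bh_adjust()`, cross-checked against
`stats::p.adjust` and exact tail enumeration in tests). Term databases are
deliberately not shipped: sets come from user GMT files, so results are
structurally, not numerically, comparable to a hosted annotation service
whose background and version cannot be pinned.

## Validation-layer statistics

Bisulfite-clone matrices (clones × CpG sites, entries 0/1/NA) summarize to
per-site and overall methylation ratios with missing calls excluded from
numerator and denominator. Group comparison aggregates to one value per
animal before testing — the animal, not the clone, is the unit of analysis,
avoiding pseudoreplication — and uses one-way ANOVA with Tukey's HSD.
Phenotype endpoints follow the conventional formulas: trapezoidal OGTT AUC
over the full measured span (minutes 0–120; the incremental area above
baseline is also reported, since either convention appears in practice),
HOMA-IR = insulin × glucose / 22.5 with units taken as given, and qPCR
relative expression by 2^−ΔΔCt against a reference gene and calibrator
group, with 100% amplification efficiency assumed (configurable base). Two
groups are compared by Student's t-test, three or more by ANOVA + Tukey.

## The synthetic-data generator

`simulate_probe_array()` emulates the structure of a deposited promoter
tiling-array series at desk scale: 500 promoters (a commercial design has
tens of thousands; 500 keeps a full run under a minute on one core), 18
probes of 60 bp at 100-bp spacing per promoter, two groups of three
replicates. Per-probe per-sample values are baseline + planted effect +
i.i.d. Gaussian noise (sd 0.3 log2 units by default; a per-probe CV target
range can replace the common sd). Promoter CpG classes are drawn at
50/25/25 HCP/ICP/LCP, and the methylation baseline is tied to class — LCP
promoters methylated (baseline log2 ratio 1.0), HCP/ICP unmethylated
(baseline 0.0) — the standard somatic-promoter picture in which high-CpG
promoters stay unmethylated while a substantial low-CpG fraction is
constitutively methylated. Planted DMRs are centered 8-probe blocks
(comfortably above the 2-probe peak minimum), 20 hyper in unmethylated
promoters and 20 hypo in methylated ones (hypomethylation needs a
methylated baseline to be both detectable and filterable), with ±1.0 log2
effects in the treatment group only. Every generator is a pure function of
(config, seed); truth files list each planted signal exactly once.

Sequence truth comes from construction rules, never from running the
classifier: HCP promoters embed a 500-bp alternating-CG block (ratio 2.0,
GC 1.0), LCP sequences contain no CG dinucleotide anywhere, and ICP
promoters embed a 500-bp block of GC 0.5 with 18 evenly spaced CpGs (ratio
≈ 0.58, between the two thresholds). Flanks are CG-free at GC 0.5 and the
junctions introduce no CG, so partial windows cannot cross a class
boundary.

What the generator does **not** emulate: dye bias, spatial artifacts,
probe-sequence affinity (including the CpG-density dependence of MeDIP
sensitivity), correlated replicate noise, and copy-number effects. Passing
tests on simulated data therefore demonstrate the correctness and
calibration of the statistics under the stated noise model, not robustness
to platform artifacts.

## Calibration results and known limitations

The acceptance script computes the pipeline's operating characteristics at
the default study conditions. With ±1.0 log2 effects over sd-0.3 noise,
sensitivity for planted DMRs is 1.0 and precision is ≈ 0.85–0.93 across
seeds; with the effect set to zero, 5–13 DEPs per ~9,000 probes survive
filtering. The source of the residual false calls is structural: the
windowed score's 1% per-probe null rate arrives in correlated runs (shared
window members), and the published two-criterion filter has no mechanism to
reject a small spurious `M'` cluster that falls inside a constitutively
methylated promoter — such a peak genuinely satisfies the median-ratio rule
in both groups, its in-direction median `M'` is positive by selection, and
at sd 0.3 the linear-scale CV (≈ 0.21) is far below the 0.8 ceiling. The
filter controls gross irreproducibility, not the false discovery rate; on
real data the DMR list should be treated as enriched for true differences,
not purified of false ones, which is exactly why downstream bisulfite
validation of individual genes is part of the design. Raising
`score_cutoff` or `min_probes`, or demanding a larger `median_ratio_min`,
trims the false calls monotonically (a test asserts the monotonicity) at
the cost of sensitivity to narrow or weak DMRs.

Other known limitations: no moderated-variance or model-based differential
test (the pipeline is a faithful implementation of the windowed-score
procedure, not a replacement for it); no multiple-testing correction across
peaks at the DEP stage; promoter classification reflects sequence
composition only, not measured methylation; and the exact peak calls of the
vendor's closed-source caller are not reproduced bit for bit — its windowed
statistic is unpublished, so the rank-sum analogue here is the package's
own, documented choice.
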