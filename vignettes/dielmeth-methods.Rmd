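---
title: "Models and methods behind dielmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dielmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`dielmeth` analyses temporal (diel) whole-genome bisulfite sequencing
together with RNA-seq in plants, in the setting of two leaf tissues — a
photosynthetic "green" tissue and a non-photosynthetic "white" tissue —
sampled at 4 am, 10 am, 4 pm and 10 pm with two biological replicates each.
The pipeline starts from per-cytosine count tables (CX-report-style TSV) and
gene-level RNA counts; read trimming, alignment and transcript assembly are
out of scope.

The package has six layers: a synthetic-study generator with planted
effects, the methylation core (contexts, QC, weighted levels, windows),
aggregate profiles, window-based DMR calling, expression quantification with
a minimal differential test, and DMR-expression integration with GO
enrichment.

# Weighted methylation

All methylation levels are *weighted*: for a region and context, the level
is `sum(methylated reads) / sum(total reads)` over covered cytosines of
that context. This coverage-weighted statistic is robust at low depth and is
additive: windows recombine exactly into larger regions by summing counts.
Zero denominators propagate as missing values, never as zero — coding an
uncovered window as 0 would fabricate hypomethylation.

Two conventions worth noting:

* **Strands are not merged.** Each strand's cytosine is an independent
  record, matching methratio-style output of bisulfite aligners. Merging CG
  pairs changes denominators; per-strand is the conservative default.
* **Truncated contexts.** A cytosine with fewer than two downstream bases on
  its own strand cannot be assigned CG/CHG unambiguously in general; such
  sites are deterministically labelled CHH. They are a negligible count (at
  most two per contig end) but determinism matters for reproducibility.

Windows are half-open, 0-based internally; the last partial window of each
chromosome is kept (and visible through its `end` column) rather than
silently dropped. Sliding windows (e.g. the 500-kb/100-kb chromosome
tracks) start at `seq(0, ceiling((L - width)/step) * step, step)`, which
covers the chromosome end with at most one trailing partial window.

# DMR calling

Differential methylation is assessed per 100-bp window and context between
two pooled sample groups. A window is a DMR iff:

1. both groups have coverage and at least `min_cytosines = 4` covered
   cytosines of the context (otherwise the window is *not assessable* and
   excluded from both numerator and denominator of any error-rate
   computation);
2. a two-sided Fisher exact test on the pooled 2x2 table
   `[[meth_A, unmeth_A], [meth_B, unmeth_B]]` is significant after
   Benjamini-Hochberg adjustment at `q <= 0.05`; and
3. the absolute difference in weighted level reaches the context threshold:
   **0.4 for CG, 0.2 for CHG, 0.1 for CHH**.

The effect-size thresholds are fixed study constants; the choice of test
and significance level is this package's own (the upstream methodology
delegates to a DMR caller without printing its settings), so both are
recorded in every output table. Replicates are pooled by summing counts —
the simplest defensible treatment at two replicates; a beta-binomial
dispersion model is a noted extension, not implemented. Adjacent
significant windows are *not* merged by default: window-level counting
matches how dense per-locus DMR counts arise in this kind of study.
`merge_dmrs()` optionally merges same-direction windows within a gap and
recomputes all statistics on the re-pooled counts; `merge_cg_strands()`
likewise offers opt-in merging of symmetric CpG strand pairs.

The Fisher engine is vectorised: two-sided p-values follow the
minimum-likelihood convention (sum of all hypergeometric outcomes no more
likely than the observed one, with a `1 + 1e-7` slack for ties), computed
from `phyper` tails after locating the opposite-tail boundary by bisection
on the unimodal pmf. It is checked in the test suite against both
`stats::fisher.test` and a full `choose()`-based enumeration over every
table with total at most 30.

Direction labels (`hyper`/`hypo`) are relative to the first-named group,
and every record carries its comparison tuple, so a swap of groups flips
directions and negates deltas but changes nothing else — a property the
tests assert.

# Profiles

Metaprofiles use 20 upstream bins of 100 bp (2 kb flank), 20 proportional
gene-body bins, and 20 downstream bins, oriented 5'→3' (minus-strand
features are reversed before binning). A cytosine at offset `d` in a body of
length `len` falls in bin `floor(n_bins * d / len)`, clamped to
`n_bins - 1`; this is deterministic and handles features shorter than the
bin count. Bins pool raw counts across features (weighted semantics); a
mean-of-features mode exists for sensitivity analysis. The flank size is
2 kb by default — the same distance used for promoters and for DMR-gene
linking — and configurable.

# Expression

FPKM is `count * 1e9 / (exonic_length * library_size)` with library size
defaulting to the column sum. Genes with FPKM > 0.5 are "expressed".
Quintile strata rank expressed genes by a chosen FPKM vector with stable
gene-id tie-breaking; the three-class mode labels unexpressed genes
(FPKM <= 0.5) and splits the expressed genes at terciles into lowly/highly
expressed, dropping the middle tercile (the low/high cutoffs are not pinned
by the source study; terciles-extremes is this package's documented
choice).

The differential test is a deliberately *minimal* negative-binomial Wald
test: median-of-ratios size factors, a single pooled method-of-moments
dispersion (ratio estimator over genes with mean >= 10, floored at 0.01),
and a Wald z on the log2 ratio of normalised group means with model-based
standard error. It is not DESeq2 — no shrinkage, no Cox-Reid dispersion, no
independent filtering — and its output metadata says so. Its calibration is
verified empirically: on a 2000-gene null with two replicates per group the
raw type-I error at 0.05 sits within [0.03, 0.07], and a planted 4-fold
change at mean 100 is detected with power above 0.9. DE status uses
`q <= 0.05` with no fold-change floor.

The Mann-Whitney test is implemented with exact enumeration over all
`choose(n1+n2, n1)` assignments of pooled mid-ranks when the combined
sample size is at most 20 — exactness in the presence of ties is needed so
that identical samples give p = 1 — and a tie-corrected,
continuity-corrected normal approximation otherwise.

# Integration

A gene and a DMR are linked iff the DMR intersects the gene body extended
by exactly 2000 bp on each side. The zone is `body` when any body overlap
exists (body takes precedence on straddles, avoiding double-zoning in
headline counts), otherwise the strand-aware flank side. The headline
DMR-associated DEG fraction deduplicates genes; the zone x context x
direction breakdown counts a gene once per stratum.

GO enrichment is an upper-tail hypergeometric test per term. Reported terms
have raw p < 0.01 with *no* multiple-testing correction — matching the
upstream procedure — and a BH column is emitted alongside for users. The
population is all genes supplied as such (in the synthetic study: all
annotated genes); this is recorded in the output because the choice of
population is not pinned by the source methodology.

# The synthetic study generator

The generator emulates the study's structure so every downstream stage has
known ground truth. Defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| genome | 2 x 1 Mb + 20 kb control contig | autosomes + unmethylated chloroplast stand-in |
| genes / TEs | 200 / 200 | genes spaced >= 5 kb (disjoint 2-kb envelopes); TEs 85% pericentromeric |
| base levels | CG 0.60, CHG 0.30, CHH 0.10 | plant-like context ordering |
| TE boost | +0.30 | hypermethylated repeats |
| tissue ΔCHH | 0.05 | CHH reduced in white tissue |
| diel CHH amplitude | ±0.05 | green tissue, + at 4 pm/10 pm, − at 4 am/10 am |
| coverage | Poisson(20) per sample | 2 replicates pooled → ~40x per group |
| conversion error | 0.012 | non-conversion rate; estimated rate ≈ 98.8% |
| planted diel DMRs | 15 / 30 / 45 (CG/CHG/CHH) | 600 bp, effects 0.4 / 0.2 / 0.1 |
| DE genes | 120 of 200, log2FC = 2 | balanced up/down between tissues |
| DMR-linked DEGs | 85% | 2 planted 800-bp tissue DMRs per linked gene |

Key modelling choices:

* **Counts.** Methylated reads are Binomial(coverage, p_obs) with
  `p_obs = p + (1 - p) * conversion_error`: bisulfite non-conversion reads a
  truly unmethylated cytosine as methylated, so the control contig (true
  p = 0) shows the configured error and the estimated conversion rate
  lands above the usual 98.7% QC bar. Sequencing miscalls are ignored. RNA
  counts are negative binomial with dispersion 0.05 and lognormal
  library-size factors.
* **Site landscape.** CG and CHG sites are drawn from a bimodal high/low
  mixture whose mean equals the configured level (plant CG methylation is
  bimodal per site); CHH is homogeneous and low. This gives windows a
  realistic between-window variance, which is what replicate correlations
  measure.
* **Planted DMRs are exact at window resolution.** Planted intervals align
  to the 100-bp grid and reset their sites to the homogeneous context base
  level (no TE boost or mixture inside), so the planted Δm is the nominal
  effect exactly. Diel-planted intervals add their effect in green at
  4 pm/10 pm; tissue-planted intervals add it to the hypermethylated tissue
  at all times. CHH diel intervals are always hyper-at-afternoon, aligned
  with the global oscillation.
* **Per-context planted counts (15/30/45)** mirror the empirical ordering
  of DMR counts (CHH most, then CHG, then CG). With effects sitting exactly
  at the calling thresholds, each context's per-window detection is ~0.5,
  so equal counts would make the CG/CHG ordering a coin flip; the
  generator's job is to emulate the study's structure, which includes that
  ordering.
* **Expression-methylation coupling.** Each gene carries a repression
  propensity `u ~ U(0,1)`: non-CG promoter methylation increases with `u`
  (up to +0.15) and expression decreases as `2^(-3u)`; genes with `u > 0.85`
  are silent. Stratified analyses therefore recover the expected pattern
  (unexpressed genes have the highest promoter non-CG methylation).
* **Balanced DE signs.** Exactly half the DE genes go up in green. With a
  large DE fraction, i.i.d. sign flips can unbalance the split enough to
  bias median-of-ratios size factors (the normalisation's median gene drifts
  into a DE block), deflating power and creating systematic false calls.
* **Two linked DMRs per linked DEG.** Real DMR-associated loci carry
  several DMRs; practically, this makes the measured DMR-associated-DEG
  fraction a faithful estimator of the planted linkage rate (a single
  interval is occasionally missed at threshold effect sizes).

What the generator does *not* emulate: read-level error profiles, mapping
artefacts, realistic sequence composition beyond context frequencies,
chromatin-state-dependent methylation, or dispersion trends in RNA counts.
Passing tests on this generator demonstrate the pipeline's correctness and
calibration under its noise model, not performance on real libraries.

# Evaluation conventions

Planted-DMR *sensitivity* counts a planted interval as recovered when at
least one called window overlaps it. The empirical *FDR* is truth-aware and
window-level: a called window is a true positive iff the generator's
noise-free methylation difference over that window reaches the context
threshold. This matters because the genome-wide diel CHH oscillation makes
thousands of windows genuinely differential (true Δ = 2 x amplitude = 0.1,
exactly the CHH threshold) in morning-vs-afternoon comparisons; counting
those as false positives would measure the generator, not the caller.
Windows that are not assessable are excluded throughout.

Tissue-contrast evaluations (the DMR-associated DEG fraction, expression
stratification) use the 10 am green-vs-white comparison — the study's own
exemplar time point — where the global diel and tissue terms cancel by
construction and the contrast is carried by the planted regional effects.
Diel evaluations use green 10 am vs 4 pm, the transition with the largest
CHH change.

# Problem sizes and reproducibility

The acceptance script (`scripts/acceptance.R`) regenerates the full default
study (2 Mb, 16 methylomes of ~1.0 M cytosine records each), calls DMRs for
the four diel comparisons and the 10 am tissue comparison, runs the DE and
integration layers, and repeats a null configuration for false-call
control, in a few minutes on one CPU. Unit tests use a 150-kb single
chromosome study. All randomness flows from a single integer seed; a rerun
with the same seed reproduces every TSV/BED output byte for byte (asserted
by checksum in the test suite).

# Known limitations

* Pooling replicates discards between-replicate overdispersion of
  methylation counts; at two replicates there is little to estimate, but
  the Fisher test can be anticonservative on real data with biological
  variability. The `min_cytosines` and Δm thresholds mitigate this.
* The NB test's pooled dispersion assumes a shared dispersion scale across
  genes; it is calibrated on the generator's homoscedastic counts and is
  not a substitute for a mean-dispersion-trend model on real data.
* GO enrichment ignores the GO DAG (no true-path propagation); terms are
  treated as flat gene sets, as in the upstream procedure.
* FPKM depends on the supplied library sizes; with the synthetic study's
  small gene universe the absolute FPKM scale is arbitrary, and only the
  expressed/unexpressed boundary and ranks matter.
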