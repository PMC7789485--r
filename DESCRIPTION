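Package: dielmeth
Title: Diel DNA Methylome and Transcriptome Integration for Plant
    Bisulfite Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis pipeline for temporal (diel) whole-genome
    bisulfite sequencing and RNA-seq studies of plant tissues. Provides
    per-context (CG/CHG/CHH) weighted methylation quantification over regions
    and fixed windows, conversion-rate and replicate-concordance QC,
    gene/transposon metaprofiles and chromosome-scale tracks, Fisher-exact
    window-based differentially methylated region (DMR) calling with
    context-specific effect-size thresholds, DMR genomic classification and
    diel state dynamics, FPKM quantification with expression stratification,
    a minimal negative-binomial differential-expression test, DMR-to-gene
    linking with hypergeometric GO enrichment, and a fully parameterised
    synthetic-study generator with planted effects and ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse,
    yaml
Config/testthat/edition: 3
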