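#' Configuration for a synthetic diel methylome + transcriptome study
#'
#' Bundles every knob of the synthetic-study generator: genome geometry,
#' baseline methylation per cytosine context, transposon and pericentromere
#' structure, the tissue contrast (CHH reduced in the non-photosynthetic
#' "white" tissue), the diel CHH oscillation in the photosynthetic "green"
#' tissue (up at 4 pm / 10 pm, down at 4 am / 10 am), planted differentially
#' methylated regions per context, sequencing depth and bisulfite
#' non-conversion, and the RNA-seq layer (negative-binomial counts with
#' planted differential expression, a fraction of it DMR-linked).
#'
#' @param seed integer seed; the same seed yields byte-identical study output.
#' @param n_chrom number of autosome-like chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param control_len length of the unmethylated control contig (chloroplast
#'   stand-in) used for conversion-rate estimation.
#' @param n_genes,n_tes number of gene models / transposable elements across
#'   the genome.
#' @param pericentromere_fraction central fraction of each chromosome that is
#'   TE-enriched ("pericentromere").
#' @param base_levels named numeric, mean methylation per context; must
#'   satisfy CHH < CHG < CG as in plant methylomes.
#' @param te_boost additive methylation inside TEs (all contexts, clipped).
#' @param tissue_chh_delta genome-wide reduction of CHH methylation in the
#'   "white" tissue.
#' @param diel_chh_amplitude half-amplitude of the genome-wide CHH diel
#'   oscillation in "green" (+ at 4 pm/10 pm, - at 4 am/10 am).
#' @param mean_coverage mean per-cytosine read depth per sample (Poisson).
#' @param conversion_error probability that an unmethylated cytosine escapes
#'   bisulfite conversion and is read as methylated.
#' @param n_planted_dmrs named integer vector: number of planted diel DMR
#'   intervals per context (single number recycled to all contexts).
#' @param planted_effect named numeric: planted methylation difference per
#'   context; defaults equal the DMR-calling thresholds (0.4/0.2/0.1).
#' @param dmr_length length (bp) of planted diel DMR intervals; multiple of
#'   100 so intervals align with the analysis window grid.
#' @param linked_dmr_length length (bp) of planted tissue-contrast DMRs
#'   attached to DMR-linked differentially expressed genes.
#' @param linked_dmrs_per_gene number of planted tissue-contrast DMRs per
#'   linked gene (real DMR-associated loci typically carry several DMRs).
#' @param n_de_genes number of genes differentially expressed between green
#'   and white (at every time point).
#' @param de_log2fc planted log2 fold change of DE genes (green vs white).
#' @param nb_dispersion negative-binomial dispersion of RNA counts.
#' @param frac_dmr_linked_degs fraction of DE genes given a planted
#'   tissue-contrast DMR within the gene body +/- 2 kb envelope.
#' @param promoter_meth_range maximum additive non-CG promoter methylation
#'   tied to a per-gene repression propensity (drives the planted
#'   expression-methylation anticorrelation).
#' @param expr_meth_log2_slope log2 expression decrease per unit of the
#'   per-gene repression propensity.
#' @param mean_expression scale (median-ish) of gene base expression counts.
#' @param library_size_cv lognormal sd of per-sample library-size factors.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_chrom = 1, chrom_len = 5e4, n_genes = 5,
#'                   n_tes = 10)
#' cfg$base_levels
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 1e6,
                       control_len = 2e4,
                       n_genes = 200L,
                       n_tes = 200L,
                       pericentromere_fraction = 0.3,
                       base_levels = c(CG = 0.6, CHG = 0.3, CHH = 0.1),
                       te_boost = 0.3,
                       tissue_chh_delta = 0.05,
                       diel_chh_amplitude = 0.05,
                       mean_coverage = 20,
                       conversion_error = 0.012,
                       n_planted_dmrs = c(CG = 15L, CHG = 30L, CHH = 45L),
                       planted_effect = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                       dmr_length = 600L,
                       linked_dmr_length = 800L,
                       linked_dmrs_per_gene = 2L,
                       n_de_genes = 120L,
                       de_log2fc = 2,
                       nb_dispersion = 0.05,
                       frac_dmr_linked_degs = 0.85,
                       promoter_meth_range = 0.15,
                       expr_meth_log2_slope = 3,
                       mean_expression = 100,
                       library_size_cv = 0.05) {
  if (length(n_planted_dmrs) == 1L && is.null(names(n_planted_dmrs)))
    n_planted_dmrs <- setNames(rep(as.integer(n_planted_dmrs), 3), .CONTEXTS)
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_len = as.numeric(chrom_len), control_len = as.numeric(control_len),
    n_genes = as.integer(n_genes), n_tes = as.integer(n_tes),
    pericentromere_fraction = pericentromere_fraction,
    base_levels = base_levels[.CONTEXTS], te_boost = te_boost,
    tissue_chh_delta = tissue_chh_delta,
    diel_chh_amplitude = diel_chh_amplitude,
    mean_coverage = mean_coverage, conversion_error = conversion_error,
    n_planted_dmrs = n_planted_dmrs[.CONTEXTS],
    planted_effect = planted_effect[.CONTEXTS],
    dmr_length = as.integer(dmr_length),
    linked_dmr_length = as.integer(linked_dmr_length),
    linked_dmrs_per_gene = as.integer(linked_dmrs_per_gene),
    n_de_genes = as.integer(n_de_genes), de_log2fc = de_log2fc,
    nb_dispersion = nb_dispersion,
    frac_dmr_linked_degs = frac_dmr_linked_degs,
    promoter_meth_range = promoter_meth_range,
    expr_meth_log2_slope = expr_meth_log2_slope,
    mean_expression = mean_expression,
    library_size_cv = library_size_cv
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  props <- c(cfg$pericentromere_fraction, cfg$base_levels, cfg$te_boost,
             cfg$tissue_chh_delta, cfg$diel_chh_amplitude,
             cfg$conversion_error, cfg$frac_dmr_linked_degs,
             cfg$planted_effect, cfg$promoter_meth_range)
  .assert(all(is.finite(props)) && all(props >= 0 & props <= 1),
          "all proportions must lie in [0, 1]")
  bl <- cfg$base_levels
  .assert(!anyNA(bl) && bl[["CHH"]] < bl[["CHG"]] && bl[["CHG"]] < bl[["CG"]],
          "base_levels must satisfy CHH < CHG < CG")
  .assert(!anyNA(cfg$n_planted_dmrs) && all(cfg$n_planted_dmrs >= 0),
          "n_planted_dmrs must be named by context (CG, CHG, CHH) and >= 0")
  .assert(cfg$mean_coverage >= 0, "mean_coverage must be >= 0")
  .assert(cfg$dmr_length %% 100L == 0L && cfg$linked_dmr_length %% 100L == 0L,
          "planted DMR lengths must be multiples of the 100-bp window grid")
  .assert(cfg$n_chrom >= 1 && cfg$chrom_len > 0, "need at least one chromosome")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("genome: %d chrom x %s bp (+%s bp control), %d genes, %d TEs",
              x$n_chrom, format(x$chrom_len, big.mark = ","),
              format(x$control_len, big.mark = ","), x$n_genes, x$n_tes),
      sprintf("base levels: CG=%.2f CHG=%.2f CHH=%.2f; TE boost %.2f",
              x$base_levels[["CG"]], x$base_levels[["CHG"]],
              x$base_levels[["CHH"]], x$te_boost),
      sprintf("tissue dCHH=%.2f, diel amp=%.2f, coverage=%g, conv.err=%.3f",
              x$tissue_chh_delta, x$diel_chh_amplitude, x$mean_coverage,
              x$conversion_error),
      sprintf("planted DMRs: CG=%d CHG=%d CHH=%d (effects %.2f/%.2f/%.2f)",
              x$n_planted_dmrs[["CG"]], x$n_planted_dmrs[["CHG"]],
              x$n_planted_dmrs[["CHH"]], x$planted_effect[["CG"]],
              x$planted_effect[["CHG"]], x$planted_effect[["CHH"]]),
      sprintf("expression: %d DE genes (log2fc %.1f), %.0f%% DMR-linked",
              x$n_de_genes, x$de_log2fc, 100 * x$frac_dmr_linked_degs),
      sep = "\n")
  invisible(x)
}

#' Sample sheet of the synthetic study design
#'
#' @return data.table with one row per BS-seq/RNA-seq sample:
#'   2 tissues x 4 time points x 2 replicates.
#' @export
sample_sheet <- function() {
  ss <- data.table::CJ(tissue = .TISSUES, time = .TIMES,
                       replicate = c("r1", "r2"), sorted = FALSE)
  ss[, time := factor(time, levels = .TIMES)]
  data.table::setorder(ss, tissue, time, replicate)
  ss[, time := as.character(time)]
  ss[, sample_id := paste(tissue, time, replicate, sep = "_")]
  data.table::setcolorder(ss, c("sample_id", "tissue", "time", "replicate"))
  ss[]
}
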