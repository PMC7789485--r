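# RNA-seq layer of the synthetic study.

#' Simulate RNA-seq counts for the study samples
#'
#' Draws a negative-binomial gene x sample count matrix for the 16 study
#' samples. Per-gene base means come from the expression plan in the ground
#' truth (lognormal, attenuated by the gene's promoter-methylation
#' repression propensity; silent genes near zero). True DE genes are shifted
#' by `de_log2fc` between green and white symmetrically (half the fold
#' change up, half down) at every time point. Per-sample library-size
#' factors are lognormal.
#'
#' @param genome a [GenomeModel].
#' @param truth ground truth from [simulate_methylome()].
#' @param cfg the study [sim_config()].
#' @return list: `counts` (gene x sample integer matrix), `gene_lengths`
#'   (named exonic lengths), `lib_factors` (named per-sample factors).
#' @export
simulate_expression <- function(genome, truth, cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  gp <- truth$genes
  ss <- sample_sheet()
  ng <- nrow(gp); ns <- nrow(ss)
  lib <- rlnorm(ns, meanlog = 0, sdlog = cfg$library_size_cv)
  names(lib) <- ss$sample_id
  counts <- matrix(0L, ng, ns, dimnames = list(gp$gene_id, ss$sample_id))
  shift <- ifelse(ss$tissue == "green", 1, -1)  # green carries +fc/2
  for (j in seq_len(ns)) {
    mu <- gp$base_mean * 2^(gp$de_sign * cfg$de_log2fc / 2 * shift[j]) * lib[j]
    counts[, j] <- rnbinom(ng, mu = mu, size = 1 / cfg$nb_dispersion)
  }
  lens <- genome$exons[, .(length_bp = sum(end - start)), by = gene_id]
  gene_lengths <- setNames(lens$length_bp, lens$gene_id)[gp$gene_id]
  list(counts = counts, gene_lengths = gene_lengths, lib_factors = lib)
}

#' Simulate a GO term-to-gene map with one planted enriched term
#'
#' Every gene receives 1-4 random terms; the planted term `GO:9999999`
#' covers 90% of true DE genes but only 10% of the remaining genes, so DE
#' gene sets are strongly enriched for it.
#'
#' @inheritParams simulate_expression
#' @param n_terms number of background GO terms.
#' @return data.table `gene_id, go_id`.
#' @export
simulate_go_map <- function(genome, truth, cfg, n_terms = 40L) {
  set.seed(cfg$seed + 3L)
  gp <- truth$genes
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  base <- data.table::rbindlist(lapply(gp$gene_id, function(g)
    data.table::data.table(gene_id = g,
                           go_id = sample(terms, sample(1:4, 1L)))))
  de <- gp$de
  pl <- runif(nrow(gp)) < ifelse(de, 0.9, 0.1)
  planted <- data.table::data.table(gene_id = gp$gene_id[pl],
                                    go_id = "GO:9999999")
  out <- unique(data.table::rbindlist(list(base, planted)))
  data.table::setorder(out, gene_id, go_id)
  out[]
}

#' Generate the complete synthetic study
#'
#' Runs [simulate_genome()], [simulate_methylome()], [simulate_expression()]
#' and [simulate_go_map()] under one configuration and optionally writes
#' every artefact to disk (genome FASTA, annotation GFF3, per-sample
#' CX-report TSVs, count/length TSVs, GO map TSV, ground-truth JSON).
#'
#' @param cfg a [sim_config()].
#' @param outdir optional output directory (created if needed).
#' @return list of class `diel_study`: `cfg, genome, calls, truth, counts,
#'   gene_lengths, lib_factors, go_map, samples`.
#' @export
simulate_study <- function(cfg = sim_config(), outdir = NULL) {
  genome <- simulate_genome(cfg)
  meth <- simulate_methylome(genome, cfg)
  expr <- simulate_expression(genome, meth$truth, cfg)
  go_map <- simulate_go_map(genome, meth$truth, cfg)
  study <- list(cfg = cfg, genome = genome, calls = meth$calls,
                truth = meth$truth, counts = expr$counts,
                gene_lengths = expr$gene_lengths,
                lib_factors = expr$lib_factors, go_map = go_map,
                samples = sample_sheet())
  class(study) <- "diel_study"
  if (!is.null(outdir)) write_study(study, outdir)
  study
}

#' @export
print.diel_study <- function(x, ...) {
  cat(sprintf(
    "<diel_study> %d samples, %s cytosine records/sample, %d genes, %d planted DMRs\n",
    length(x$calls), format(nrow(x$calls[[1]]), big.mark = ","),
    nrow(x$genome$genes), nrow(x$truth$planted)))
  invisible(x)
}

#' Write all study artefacts to a directory
#'
#' @param study a `diel_study` from [simulate_study()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(study$genome$seqs, file.path(outdir, "genome.fa"))
  write_gff3(study$genome, file.path(outdir, "annotation.gff3"))
  cxdir <- file.path(outdir, "cx"); dir.create(cxdir, showWarnings = FALSE)
  for (sid in names(study$calls))
    write_cx(study$calls[[sid]], file.path(cxdir, paste0(sid, ".cx.tsv")))
  cm <- data.table::as.data.table(study$counts, keep.rownames = "gene_id")
  data.table::fwrite(cm, file.path(outdir, "rna_counts.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(gene_id = names(study$gene_lengths),
                           length_bp = study$gene_lengths),
    file.path(outdir, "gene_lengths.tsv"), sep = "\t")
  data.table::fwrite(study$go_map, file.path(outdir, "go_map.tsv"),
                     sep = "\t")
  truth <- study$truth
  jsonlite::write_json(
    list(control_contig = truth$control_contig,
         window_width = truth$window_width,
         planted = truth$planted,
         genes = truth$genes),
    file.path(outdir, "ground_truth.json"),
    dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(outdir)
}
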