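# Study-level orchestration: group pooling, standard comparisons and
# planted-truth evaluation.

#' Pooled window table for one tissue/time group
#'
#' Pools the replicates of a (tissue, time) group by summing counts, then
#' windows the pooled call set.
#'
#' @param study a `diel_study`.
#' @param tissue `"green"` or `"white"`.
#' @param time one of `"4am"`, `"10am"`, `"4pm"`, `"10pm"`.
#' @param width window width (default 100).
#' @return a WindowTable.
#' @export
group_windows <- function(study, tissue, time, width = 100L) {
  ss <- study$samples
  tis <- tissue; tm <- time
  ids <- ss[ss$tissue == tis & ss$time == tm, sample_id]
  .assert(length(ids) > 0, "no samples for this group")
  pooled <- pool_calls(study$calls[ids])
  make_windows(pooled, study$genome$seqlens, width = width)
}

#' DMRs for one group-vs-group comparison of the study
#'
#' @param study a `diel_study`.
#' @param group_a,group_b group labels `"tissue_time"`, e.g. `"green_10am"`.
#' @param contexts contexts to call (default all three).
#' @inheritParams call_dmrs
#' @return named list of DMR tables, one per context.
#' @export
study_dmrs <- function(study, group_a, group_b, contexts = .CONTEXTS,
                       thresholds = dmr_thresholds(), alpha = 0.05,
                       min_cytosines = 4L, width = 100L) {
  pa <- strsplit(group_a, "_")[[1]]; pb <- strsplit(group_b, "_")[[1]]
  wa <- group_windows(study, pa[1], pa[2], width)
  wb <- group_windows(study, pb[1], pb[2], width)
  setNames(lapply(contexts, function(ctx)
    call_dmrs(wa, wb, ctx, thresholds, alpha, min_cytosines,
              comparison = c(group_a, group_b))), contexts)
}

#' The four successive diel comparisons of one tissue
#'
#' 10am vs 4pm, 4pm vs 10pm, 10pm vs 4am, 4am vs 10am (next day), the
#' chronological chain used for DMR dynamics.
#'
#' @param tissue tissue label.
#' @return data.table `label, group_a, group_b`.
#' @export
diel_comparisons <- function(tissue = "green") {
  chain <- c("10am", "4pm", "10pm", "4am", "10am")
  data.table::data.table(
    label = paste(chain[-length(chain)], chain[-1], sep = "_to_"),
    group_a = paste(tissue, chain[-length(chain)], sep = "_"),
    group_b = paste(tissue, chain[-1], sep = "_"))
}

# noise-free |delta m| per window between two groups, from stored truth
.truth_delta <- function(truth, group_a, group_b, context) {
  wt <- truth$window_truth
  ctx <- context; ga <- group_a; gb <- group_b
  a <- wt[wt$group == ga & wt$context == ctx,
          .(chrom, start, p_a = p_true)]
  b <- wt[wt$group == gb & wt$context == ctx,
          .(chrom, start, p_b = p_true)]
  ab <- merge(a, b, by = c("chrom", "start"))
  ab[, delta := p_a - p_b]
  ab[]
}

#' Evaluate DMR calls against the planted ground truth
#'
#' Sensitivity is the fraction of planted intervals (of the requested kind
#' and context) overlapped by at least one called DMR window. The empirical
#' FDR is truth-aware and window-level: a called window counts as a true
#' positive iff the generator's noise-free methylation difference over that
#' window reaches the context threshold (planted windows and any genuinely
#' differential background, such as the genome-wide diel CHH oscillation,
#' both qualify); windows not assessable in the calls are excluded.
#'
#' @param dmrs DMR table for one context and comparison.
#' @param study the `diel_study`.
#' @param group_a,group_b the compared groups (`"tissue_time"` labels).
#' @param context the context.
#' @param kind planted-DMR kind whose recovery is measured (`"diel"` or
#'   `"tissue"`).
#' @param thresholds context thresholds (for the truth criterion).
#' @return list `sensitivity, fdr, n_planted, n_recovered, n_called,
#'   n_false`.
#' @export
evaluate_dmr_recovery <- function(dmrs, study, group_a, group_b, context,
                                  kind = "diel",
                                  thresholds = dmr_thresholds()) {
  truth <- study$truth
  ctx <- context; knd <- kind
  pl <- truth$planted[truth$planted$context == ctx &
                        truth$planted$kind == knd]
  n_planted <- nrow(pl)
  recovered <- 0L
  if (n_planted > 0L && nrow(dmrs) > 0L) {
    data.table::setkey(pl, chrom, start, end)
    ov <- data.table::foverlaps(dmrs[, .(chrom, start, end)], pl,
                                type = "any", nomatch = NULL, which = TRUE)
    recovered <- data.table::uniqueN(ov$yid)
  }
  td <- .truth_delta(truth, group_a, group_b, context)
  called <- dmrs[, .(chrom, start)]
  n_called <- nrow(called)
  n_false <- 0L
  if (n_called > 0L) {
    chk <- merge(called, td, by = c("chrom", "start"), all.x = TRUE)
    n_false <- sum(is.na(chk$delta) |
                     abs(chk$delta) < thresholds[[context]] - 1e-9)
  }
  list(sensitivity = if (n_planted > 0) recovered / n_planted else NA_real_,
       fdr = if (n_called > 0) n_false / n_called else 0,
       n_planted = n_planted, n_recovered = recovered,
       n_called = n_called, n_false = n_false)
}

#' Green-vs-white differential expression at every time point, plus union
#'
#' Runs [de_test()] for the tissue contrast at each of the four time points
#' and forms the union DEG set (a gene is a union DEG if significant at any
#' time point), alongside the per-time-point tables.
#'
#' @param study a `diel_study`.
#' @param alpha significance level passed to [de_test()].
#' @return list: `per_time` (named list of DE tables) and `union_degs`
#'   (data.table `gene_id, times` listing the time points at which each
#'   union DEG is significant).
#' @export
de_all_times <- function(study, alpha = 0.05) {
  ss <- study$samples
  per_time <- lapply(setNames(.TIMES, .TIMES), function(tm) {
    de_test(study$counts[, ss[ss$tissue == "green" & ss$time == tm,
                              sample_id]],
            study$counts[, ss[ss$tissue == "white" & ss$time == tm,
                              sample_id]],
            alpha = alpha)
  })
  hits <- data.table::rbindlist(lapply(.TIMES, function(tm)
    per_time[[tm]][status != "ns", .(gene_id, time = tm)]))
  union_degs <- if (nrow(hits))
    hits[, .(times = paste(time, collapse = ",")), by = gene_id]
  else data.table::data.table(gene_id = character(), times = character())
  data.table::setorder(union_degs, gene_id)
  list(per_time = per_time, union_degs = union_degs[])
}

#' Run the standard analysis over a study and write its outputs
#'
#' The canonical end-to-end pass used for reproducibility checks: pooled
#' per-group windows, the four green diel DMR comparisons plus the 10 am
#' tissue comparison (all contexts), feature classification, DE at 10 am,
#' DMR-DEG links, and GO enrichment of DMR-associated DEGs; everything is
#' written as deterministic TSV/BED alongside the study artefacts.
#'
#' @param study a `diel_study`.
#' @param outdir output directory.
#' @return list of result tables, invisibly; files under `outdir`.
#' @export
run_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_study(study, outdir)

  dmrdir <- file.path(outdir, "dmrs"); dir.create(dmrdir, showWarnings = FALSE)
  cmps <- diel_comparisons("green")
  cmps <- rbind(cmps, data.table::data.table(
    label = "green_vs_white_10am", group_a = "green_10am",
    group_b = "white_10am"))
  dmr_sets <- list()
  for (i in seq_len(nrow(cmps))) {
    dl <- study_dmrs(study, cmps$group_a[i], cmps$group_b[i])
    dl <- lapply(dl, classify_dmr_features, genome = study$genome)
    dmr_sets[[cmps$label[i]]] <- dl
    flat <- data.table::rbindlist(dl)
    data.table::fwrite(flat, file.path(dmrdir,
                                       paste0(cmps$label[i], ".dmrs.tsv")),
                       sep = "\t")
    write_bed(flat, file.path(dmrdir, paste0(cmps$label[i], ".dmrs.bed")))
  }

  ss <- study$samples
  ids_a <- ss[tissue == "green" & time == "10am", sample_id]
  ids_b <- ss[tissue == "white" & time == "10am", sample_id]
  de <- de_test(study$counts[, ids_a], study$counts[, ids_b])
  data.table::fwrite(de, file.path(outdir, "de_green_vs_white_10am.tsv"),
                     sep = "\t")

  tissue_dmrs <- data.table::rbindlist(dmr_sets[["green_vs_white_10am"]])
  links <- link_dmrs_to_genes(tissue_dmrs, study$genome)
  data.table::fwrite(links, file.path(outdir, "dmr_gene_links.tsv"),
                     sep = "\t")
  assoc <- dmr_associated_degs(links, de)
  data.table::fwrite(assoc$summary, file.path(outdir,
                                              "dmr_associated_degs.tsv"),
                     sep = "\t")
  study_ids <- intersect(de[status != "ns", gene_id], unique(links$gene_id))
  pop <- study$truth$genes$gene_id
  enr <- go_enrichment(study_ids, pop, study$go_map, p_cut = 0.01)
  data.table::fwrite(enr, file.path(outdir, "go_enrichment.tsv"), sep = "\t")

  invisible(list(dmrs = dmr_sets, de = de, links = links, assoc = assoc,
                 enrichment = enr))
}
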