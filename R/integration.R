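# DMR-gene joining, DMR-associated DEG tables, GO enrichment and per-gene
# methylation dynamics.

#' Link DMRs to genes within a +/- 2 kb envelope
#'
#' A gene and a DMR are linked iff the DMR interval intersects the gene body
#' extended by exactly `flank` bp on each side. The zone is determined by
#' the overlapped portion: `"body"` takes precedence when a DMR straddles
#' body and flank; flank zones are strand-aware (`"upstream"` is 5' of the
#' TSS).
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param genome a [GenomeModel].
#' @param flank envelope extension (default 2000).
#' @return data.table `gene_id, chrom, start, end, context, direction, zone,
#'   comparison_a, comparison_b` — one row per (gene, DMR) pair.
#' @export
link_dmrs_to_genes <- function(dmrs, genome, flank = 2000L) {
  empty <- data.table::data.table(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), context = character(), direction = character(),
    zone = character(), comparison_a = character(),
    comparison_b = character())
  if (nrow(dmrs) == 0L || nrow(genome$genes) == 0L) return(empty)
  g <- genome$genes
  env <- g[, .(gene_id, chrom, strand, gstart = start, gend = end,
               start = pmax(0L, start - flank), end = end + flank)]
  data.table::setkey(env, chrom, start, end)
  q <- dmrs[, .(chrom, start, end)]
  q[, xid := .I]
  ov <- data.table::foverlaps(q, env, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(empty)
  # zone from the overlapped portion; body wins on straddle
  body_ov <- pmin(ov$i.end, ov$gend) - pmax(ov$i.start, ov$gstart)
  zone <- ifelse(body_ov > 0, "body",
          ifelse(ov$i.end <= ov$gstart,
                 ifelse(ov$strand == "+", "upstream", "downstream"),
                 ifelse(ov$strand == "+", "downstream", "upstream")))
  out <- data.table::data.table(
    gene_id = ov$gene_id,
    chrom = ov$chrom,
    start = dmrs$start[ov$xid], end = dmrs$end[ov$xid],
    context = dmrs$context[ov$xid], direction = dmrs$direction[ov$xid],
    zone = zone,
    comparison_a = dmrs$comparison_a[ov$xid],
    comparison_b = dmrs$comparison_b[ov$xid])
  unique(out)
}

#' Cross-tabulate DMR-associated differentially expressed genes
#'
#' @param links output of [link_dmrs_to_genes()] for one comparison.
#' @param de output of [de_test()] for the same comparison.
#' @return list: `summary` (data.table with DEG count, DMR-associated DEG
#'   count and headline fraction, genes deduplicated) and `breakdown`
#'   (counts per zone x context x DE direction; a gene with several links
#'   appears once per stratum).
#' @export
dmr_associated_degs <- function(links, de) {
  degs <- de[status != "ns"]
  assoc <- unique(links$gene_id)
  n_deg <- nrow(degs)
  n_assoc <- sum(degs$gene_id %in% assoc)
  summary <- data.table::data.table(
    n_deg = n_deg, n_dmr_associated = n_assoc,
    fraction = if (n_deg > 0) n_assoc / n_deg else NA_real_)
  lk <- unique(links[, .(gene_id, zone, context)])
  lk <- merge(lk, degs[, .(gene_id, status)], by = "gene_id")
  breakdown <- if (nrow(lk))
    lk[, .(n_genes = data.table::uniqueN(gene_id)),
       by = .(zone, context, status)]
  else data.table::data.table(zone = character(), context = character(),
                              status = character(), n_genes = integer())
  data.table::setorder(breakdown, zone, context, status)
  list(summary = summary, breakdown = breakdown[])
}

#' Hypergeometric GO term enrichment
#'
#' Upper-tail hypergeometric test per term: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)` for `k` study hits among `n` study genes,
#' `K` population hits among `N` population genes. No multiple-testing
#' correction is applied to the reported cutoff (matching the study's
#' procedure); a BH column is emitted for convenience.
#'
#' @param study_genes character vector of study gene ids (subset of
#'   population).
#' @param population_genes character vector of population gene ids.
#' @param go_map data.table/data.frame `gene_id, go_id`.
#' @param p_cut report terms with `p < p_cut` (default 0.01); `p_cut = 1`
#'   reports everything.
#' @return data.table `go_id, k, n, K, N, enrichment, p_value, q_value`,
#'   sorted by ascending p, filtered to `p < p_cut`. Terms with `K = 0` are
#'   skipped.
#' @export
go_enrichment <- function(study_genes, population_genes, go_map,
                          p_cut = 0.01) {
  gm <- data.table::as.data.table(go_map)
  .assert(all(c("gene_id", "go_id") %in% names(gm)),
          "go_map needs gene_id and go_id columns")
  pop <- unique(population_genes)
  study <- unique(study_genes)
  .assert(all(study %in% pop), "study genes must be a subset of the population")
  gm <- unique(gm[gene_id %in% pop, .(gene_id, go_id)])
  N <- length(pop); n <- length(study)
  tb <- gm[, .(K = data.table::uniqueN(gene_id),
               k = data.table::uniqueN(gene_id[gene_id %in% study])),
           by = go_id]
  tb <- tb[K > 0L]
  tb[, p_value := phyper(k - 1, K, N - K, n, lower.tail = FALSE)]
  tb[, `:=`(n = n, N = N,
            enrichment = ifelse(K > 0 & n > 0, (k / n) / (K / N), NA_real_))]
  tb[, q_value := bh_adjust(p_value)]
  out <- if (p_cut >= 1) tb else tb[p_value < p_cut]
  data.table::setorder(out, p_value, go_id)
  data.table::setcolorder(out, c("go_id", "k", "n", "K", "N", "enrichment",
                                 "p_value", "q_value"))
  out[]
}

#' Methylation summarised by expression stratum, with pairwise tests
#'
#' Joins per-gene region methylation levels to expression strata and, per
#' (region, context), compares every pair of strata with the Mann-Whitney
#' test.
#'
#' @param region_levels output of [region_level_table()] on genes
#'   (`feature_id` = gene id).
#' @param strata output of [expression_strata()].
#' @param alternative alternative passed to [mannwhitney()].
#' @return list: `summary` (`stratum, region, context, n, median_m`) and
#'   `tests` (`region, context, stratum_1, stratum_2, p_value`; pairs with
#'   fewer than 2 genes on either side are skipped with `NA`).
#' @export
methylation_by_expression <- function(region_levels, strata,
                                      alternative = "two.sided") {
  dt <- merge(region_levels, strata[, .(gene_id, stratum)],
              by.x = "feature_id", by.y = "gene_id")
  dt <- dt[!is.na(stratum) & !is.na(m)]
  summary <- dt[, .(n = .N, median_m = median(m)),
                by = .(stratum, region, context)]
  data.table::setorder(summary, region, context, stratum)
  lv <- sort(unique(dt$stratum))
  pairs <- if (length(lv) >= 2L) utils::combn(lv, 2L, simplify = FALSE)
           else list()
  tests <- data.table::rbindlist(lapply(pairs, function(pr) {
    dt[, {
      x <- m[stratum == pr[1L]]; y <- m[stratum == pr[2L]]
      p <- if (length(x) >= 2L && length(y) >= 2L)
        mannwhitney(x, y, alternative) else NA_real_
      .(stratum_1 = pr[1L], stratum_2 = pr[2L], n_1 = length(x),
        n_2 = length(y), p_value = p)
    }, by = .(region, context)]
  }))
  list(summary = summary[], tests = tests[])
}

#' Per-gene binned methylation across samples
#'
#' For each requested gene: 20 upstream bins (100 bp), 20 proportional body
#' bins and 20 downstream bins, per context and per sample, concatenated
#' 5'->3' in gene orientation — the heatmap-ready per-gene dynamics matrix.
#' Also returns the DMR overlaps of each gene's envelope when a DMR table is
#' supplied (genome-browser-style export).
#'
#' @param calls_by_sample named list of call sets.
#' @param genome a [GenomeModel].
#' @param gene_ids genes to profile (must exist in the annotation).
#' @param dmrs optional DMR table to intersect with the gene envelopes.
#' @param n_bins bins per zone (default 20).
#' @param flank flank width (default 2000).
#' @return list: `bins` (data.table `gene_id, sample_id, context, zone, bin,
#'   bin_index, m`; `bin_index` runs 1..3*n_bins 5'->3') and `dmr_overlaps`
#'   (possibly empty).
#' @export
gene_bin_dynamics <- function(calls_by_sample, genome, gene_ids,
                              dmrs = NULL, n_bins = 20L, flank = 2000L) {
  missing_ids <- setdiff(gene_ids, genome$genes$gene_id)
  if (length(missing_ids))
    stop("unknown gene id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  feats <- genome$genes[gene_id %in% gene_ids]
  .assert(flank == 100L * n_bins,
          "flank must equal 100 * n_bins so all three zones have n_bins bins")
  parts <- lapply(names(calls_by_sample), function(sid) {
    dt <- .assign_bins(calls_by_sample[[sid]], feats, as.integer(flank),
                       as.integer(n_bins))
    if (is.null(dt)) return(NULL)
    agg <- dt[, .(sum_meth = sum(as.numeric(n_meth)),
                  sum_total = sum(as.numeric(n_total))),
              by = .(feature_id, context, zone, bin)]
    agg[, sample_id := sid]
    agg
  })
  bins <- data.table::rbindlist(parts)
  grid <- data.table::CJ(gene_id = gene_ids,
                         sample_id = names(calls_by_sample),
                         context = .CONTEXTS,
                         zone = c("upstream", "body", "downstream"),
                         bin = seq_len(n_bins), sorted = FALSE)
  bins <- merge(grid, bins,
                by.x = c("gene_id", "sample_id", "context", "zone", "bin"),
                by.y = c("feature_id", "sample_id", "context", "zone", "bin"),
                all.x = TRUE)
  bins[, m := ifelse(!is.na(sum_total) & sum_total > 0,
                     sum_meth / sum_total, NA_real_)]
  zord <- c(upstream = 0L, body = 1L, downstream = 2L)
  bins[, bin_index := zord[zone] * n_bins + bin]
  data.table::setorder(bins, gene_id, sample_id, context, bin_index)
  data.table::setcolorder(bins, c("gene_id", "sample_id", "context", "zone",
                                  "bin", "bin_index", "sum_meth", "sum_total",
                                  "m"))
  dmr_ov <- if (!is.null(dmrs) && nrow(dmrs))
    link_dmrs_to_genes(dmrs, genome, flank)[gene_id %in% gene_ids]
  else NULL
  list(bins = bins[], dmr_overlaps = dmr_ov)
}
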