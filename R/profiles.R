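# Aggregate methylation summaries: gene/TE metaplots, chromosome tracks and
# per-feature region-level tables.
#
# Bin aggregation pools raw counts across features (sum meth / sum total),
# matching weighted-methylation semantics; a mean-of-features mode is
# available for sensitivity analysis. Body bins are proportional: a cytosine
# at offset d in a feature of length len falls in bin
# floor(n_bins * d / len), clamped to n_bins - 1.

# map each call in the feature +/- flank envelope to a (zone, bin),
# oriented 5'->3' in feature direction
.assign_bins <- function(calls, features, flank, n_bins, flank_bin = 100L) {
  .assert(flank %% flank_bin == 0L, "flank must be divisible by the flank bin size")
  n_flank_bins <- as.integer(flank / flank_bin)
  f <- data.table::as.data.table(features)
  .assert(all(c("chrom", "start", "end", "strand") %in% names(f)),
          "features need chrom, start, end, strand")
  if (!"feature_id" %in% names(f)) {
    idcol <- intersect(c("gene_id", "te_id"), names(f))
    f[, feature_id := if (length(idcol)) get(idcol[1L]) else
      sprintf("feat%06d", .I)]
  }
  env <- f[, .(feature_id, chrom, strand, fstart = start, fend = end,
               start = start - flank, end = end + flank)]
  data.table::setkey(env, chrom, start, end)
  q <- calls[, .(chrom, start = pos - 1L, end = pos)]
  ov <- data.table::foverlaps(q, env, type = "any", nomatch = NULL,
                              which = TRUE)
  if (nrow(ov) == 0L) return(NULL)
  dt <- data.table::data.table(
    feature_id = env$feature_id[ov$yid],
    strand = env$strand[ov$yid],
    fstart = env$fstart[ov$yid], fend = env$fend[ov$yid],
    pos0 = calls$pos[ov$xid] - 1L,           # 0-based site coordinate
    context = as.character(calls$context[ov$xid]),
    n_meth = calls$n_meth[ov$xid], n_total = calls$n_total[ov$xid])

  len <- dt$fend - dt$fstart
  plus <- dt$strand != "-"
  # signed distance from feature 5' end, in feature orientation
  d5 <- ifelse(plus, dt$pos0 - dt$fstart, dt$fend - 1L - dt$pos0)
  zone <- ifelse(d5 < 0, "upstream", ifelse(d5 >= len, "downstream", "body"))
  bin <- integer(nrow(dt))
  iu <- zone == "upstream"
  bin[iu] <- n_flank_bins + 1L + (d5[iu] %/% flank_bin)   # -flank..-1 -> 1..K
  ib <- zone == "body"
  bin[ib] <- pmin(n_bins - 1L, (n_bins * d5[ib]) %/% len[ib]) + 1L
  id <- zone == "downstream"
  bin[id] <- ((d5[id] - len[id]) %/% flank_bin) + 1L
  dt[, `:=`(zone = zone, bin = as.integer(bin))]
  dt
}

#' Metaprofile of methylation over a feature set
#'
#' Aggregates methylation into 5'->3' oriented bins: `flank/100` upstream
#' bins of 100 bp, `n_bins` proportional gene-body bins, and `flank/100`
#' downstream bins. Minus-strand features are reversed before binning.
#'
#' @param calls a call set.
#' @param features data.table of stranded intervals (`chrom, start, end,
#'   strand`, 0-based half-open) plus an id column.
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"all"`.
#' @param flank flank size in bp (default 2000, giving 20 flank bins).
#' @param n_bins number of proportional body bins (default 20).
#' @param mode `"pooled"` (default: sum counts across features per bin) or
#'   `"mean"` (average per-feature bin levels).
#' @return data.table `zone, bin, n_features, sum_meth, sum_total, m`,
#'   ordered upstream -> body -> downstream, bins 5'->3'.
#' @export
feature_metaprofile <- function(calls, features, context = "all",
                                flank = 2000L, n_bins = 20L,
                                mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  zones <- c("upstream", "body", "downstream")
  if (nrow(features) == 0L)
    return(data.table::data.table(zone = character(), bin = integer(),
                                  n_features = integer(), sum_meth = numeric(),
                                  sum_total = numeric(), m = numeric()))
  dt <- .assign_bins(calls, features, as.integer(flank), as.integer(n_bins))
  grid <- data.table::rbindlist(list(
    data.table::CJ(zone = "upstream", bin = seq_len(flank %/% 100L)),
    data.table::CJ(zone = "body", bin = seq_len(n_bins)),
    data.table::CJ(zone = "downstream", bin = seq_len(flank %/% 100L))))
  if (is.null(dt)) {
    out <- grid
    out[, `:=`(n_features = 0L, sum_meth = 0, sum_total = 0, m = NA_real_)]
  } else {
    ctx <- context
    if (ctx != "all") dt <- dt[dt$context == ctx]
    if (mode == "pooled") {
      agg <- dt[, .(n_features = data.table::uniqueN(feature_id),
                    sum_meth = sum(as.numeric(n_meth)),
                    sum_total = sum(as.numeric(n_total))),
                by = .(zone, bin)]
      out <- merge(grid, agg, by = c("zone", "bin"), all.x = TRUE)
      out[is.na(sum_total), `:=`(n_features = 0L, sum_meth = 0, sum_total = 0)]
      out[, m := ifelse(sum_total > 0, sum_meth / sum_total, NA_real_)]
    } else {
      per <- dt[, .(m = {
        tt <- sum(as.numeric(n_total))
        if (tt > 0) sum(as.numeric(n_meth)) / tt else NA_real_
      }), by = .(feature_id, zone, bin)]
      agg <- per[!is.na(m), .(n_features = .N, m = mean(m)), by = .(zone, bin)]
      out <- merge(grid, agg, by = c("zone", "bin"), all.x = TRUE)
      out[is.na(n_features), n_features := 0L]
      out[, `:=`(sum_meth = NA_real_, sum_total = NA_real_)]
    }
  }
  out[, zone := factor(zone, levels = zones)]
  data.table::setorder(out, zone, bin)
  out[, zone := as.character(zone)]
  out[]
}

#' Chromosome-scale methylation and feature-density track
#'
#' Combines large sliding-window methylation levels (the 500-kb / 100-kb
#' convention) with per-window gene and TE counts, suitable for circos-style
#' export.
#'
#' @param calls a call set (typically pooled replicates).
#' @param genome a [GenomeModel].
#' @param width,step window geometry (defaults 500 kb / 100 kb).
#' @return data.table `chrom, start, end, n_genes, n_tes, m_CG, m_CHG, m_CHH`.
#' @export
chromosome_track <- function(calls, genome, width = 500000L, step = 100000L) {
  seqlens <- genome$seqlens[setdiff(names(genome$seqlens),
                                    genome$control_contig)]
  wt <- make_windows(calls[chrom %in% names(seqlens)], seqlens,
                     width = width, step = step)
  wide <- data.table::dcast(wt, chrom + start + end ~ context, value.var = "m")
  data.table::setnames(wide, .CONTEXTS, paste0("m_", .CONTEXTS))
  count_in <- function(feat) {
    if (nrow(feat) == 0L)
      return(integer(nrow(wide)))
    f <- data.table::as.data.table(feat)[, .(chrom, start, end)]
    data.table::setkey(f, chrom, start, end)
    ov <- data.table::foverlaps(wide[, .(chrom, start, end)], f,
                                type = "any", nomatch = NULL, which = TRUE)
    n <- integer(nrow(wide))
    if (nrow(ov)) {
      tb <- table(ov$xid)
      n[as.integer(names(tb))] <- as.integer(tb)
    }
    n
  }
  wide[, n_genes := count_in(genome$genes)]
  wide[, n_tes := count_in(genome$tes)]
  data.table::setcolorder(wide, c("chrom", "start", "end", "n_genes", "n_tes",
                                  paste0("m_", .CONTEXTS)))
  data.table::setorder(wide, chrom, start)
  wide[]
}

#' Per-feature methylation levels in body and flanking regions
#'
#' One weighted methylation level per feature, region (gene body, 2-kb
#' upstream, 2-kb downstream; strand-aware) and context. Flanks truncated at
#' chromosome boundaries are flagged.
#'
#' @param calls a call set.
#' @param features stranded feature table (`feature_id`/`gene_id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param seqlens named chromosome lengths.
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"all"`.
#' @param flank flank width (default 2000).
#' @return data.table `feature_id, region, context, n_cytosines, sum_meth,
#'   sum_total, m, truncated` with region in
#'   `c("upstream2k", "body", "downstream2k")`.
#' @export
region_level_table <- function(calls, features, seqlens, context = "all",
                               flank = 2000L) {
  f <- data.table::as.data.table(features)
  if (!"feature_id" %in% names(f)) {
    idcol <- intersect(c("gene_id", "te_id"), names(f))
    .assert(length(idcol) > 0, "features need an id column")
    data.table::setnames(f, idcol[1L], "feature_id")
  }
  fl <- .gene_flanks(f[, .(gene_id = feature_id, chrom, start, end, strand)],
                     seqlens, flank)
  regions <- data.table::rbindlist(list(
    f[, .(feature_id, chrom, start, end, region = "body", truncated = FALSE)],
    fl$upstream[, .(feature_id = gene_id, chrom, start, end,
                    region = "upstream2k", truncated)],
    fl$downstream[, .(feature_id = gene_id, chrom, start, end,
                      region = "downstream2k", truncated)]))
  regions <- regions[end > start]
  data.table::setkey(regions, chrom, start, end)
  q <- calls[, .(chrom, start = pos - 1L, end = pos)]
  ov <- data.table::foverlaps(q, regions, type = "any", nomatch = NULL,
                              which = TRUE)
  hits <- data.table::data.table(
    feature_id = regions$feature_id[ov$yid],
    region = regions$region[ov$yid],
    context = as.character(calls$context[ov$xid]),
    n_meth = calls$n_meth[ov$xid], n_total = calls$n_total[ov$xid])
  ctx <- context
  if (ctx != "all") hits <- hits[hits$context == ctx]
  agg <- hits[, .(n_cytosines = sum(n_total > 0),
                  sum_meth = sum(as.numeric(n_meth)),
                  sum_total = sum(as.numeric(n_total))),
              by = .(feature_id, region, context)]
  grid <- data.table::CJ(feature_id = unique(f$feature_id),
                         region = c("upstream2k", "body", "downstream2k"),
                         context = if (context == "all") .CONTEXTS else context,
                         sorted = FALSE)
  out <- merge(grid, agg, by = c("feature_id", "region", "context"),
               all.x = TRUE)
  out[is.na(n_cytosines), `:=`(n_cytosines = 0L, sum_meth = 0, sum_total = 0)]
  out[, m := ifelse(sum_total > 0, sum_meth / sum_total, NA_real_)]
  out <- merge(out, unique(regions[, .(feature_id, region, truncated)]),
               by = c("feature_id", "region"), all.x = TRUE)
  out[is.na(truncated), truncated := TRUE]  # region absent (fully truncated)
  data.table::setorder(out, feature_id, region, context)
  out[]
}
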