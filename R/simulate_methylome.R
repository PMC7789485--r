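# Synthetic methylome generator.
#
# Per-site true methylation probabilities are built in layers:
#   base level per context (CG/CHG sites drawn from a bimodal high/low
#   mixture whose mean equals the configured level; CHH homogeneous)
#   + TE boost inside transposons
#   + per-gene non-CG promoter boost tied to a repression propensity u
#   + tissue term (CHH reduced in "white")
#   + diel term (CHH oscillation in "green": up 4pm/10pm, down 4am/10am)
#   + planted DMR effects.
# Inside planted intervals, sites of the interval's context are reset to the
# homogeneous context base level and carry only the planted contrast, so the
# planted delta-m is exact at window resolution. Observed methylated counts
# are Binomial(coverage, p + (1-p) * conversion_error): bisulfite
# non-conversion reads a truly unmethylated cytosine as methylated. The
# control contig has true p = 0 everywhere.

# mixture endpoints for bimodal CG/CHG site landscapes
.MIX <- list(CG = c(lo = 0.05, hi = 0.95), CHG = c(lo = 0.02, hi = 0.85))

#' Simulate per-cytosine methylation counts for all study samples
#'
#' Draws the full BS-seq layer of the synthetic study: one cytosine call set
#' per sample (2 tissues x 4 time points x 2 replicates) plus the ground
#' truth (planted DMR intervals, true DE genes, per-gene expression plan,
#' and noise-free window-level methylation per sample group).
#'
#' @param genome a [GenomeModel] from [simulate_genome()].
#' @param cfg the [sim_config()] used to build `genome`.
#' @param window_width width (bp) at which noise-free window truth is
#'   recorded; matches the default DMR analysis grid.
#' @return list with elements `calls` (named list of call-set data.tables,
#'   one per sample: `chrom, pos, strand, context, n_meth, n_total`) and
#'   `truth` (see Details).
#' @details `truth` is a list: `planted` (planted DMR intervals with context,
#'   kind `"diel"`/`"tissue"`, direction and linked gene), `genes` (per-gene
#'   repression propensity `u_gene`, base expression mean, silent flag, DE
#'   status/sign, DMR-linked flag), `window_truth` (noise-free mean
#'   methylation per window, context and tissue/time group),
#'   `control_contig`, and `window_width`. All truth intervals are 0-based
#'   half-open.
#' @export
simulate_methylome <- function(genome, cfg, window_width = 100L) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)

  sites <- .build_sites(genome, cfg)
  plan <- .plan_truth(genome, cfg)
  sites <- .apply_planted(sites, plan$planted, cfg)
  sites <- .apply_promoter_boost(sites, genome, plan$genes, cfg)

  groups <- data.table::CJ(tissue = .TISSUES, time = .TIMES, sorted = FALSE)
  group_p <- vector("list", nrow(groups))
  names(group_p) <- paste(groups$tissue, groups$time, sep = "_")
  for (i in seq_len(nrow(groups)))
    group_p[[i]] <- .site_group_p(sites, plan$planted,
                                  groups$tissue[i], groups$time[i], cfg)

  window_truth <- .window_truth(sites, group_p, window_width)

  ss <- sample_sheet()
  calls <- vector("list", nrow(ss))
  names(calls) <- ss$sample_id
  n <- nrow(sites)
  for (i in seq_len(nrow(ss))) {
    p <- group_p[[paste(ss$tissue[i], ss$time[i], sep = "_")]]
    p_obs <- p + (1 - p) * cfg$conversion_error
    cov <- rpois(n, cfg$mean_coverage)
    meth <- rbinom(n, cov, p_obs)
    calls[[i]] <- data.table::data.table(
      chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
      context = as.character(sites$context),
      n_meth = meth, n_total = cov)
  }

  truth <- list(planted = plan$planted, genes = plan$genes,
                window_truth = window_truth,
                control_contig = genome$control_contig,
                window_width = as.integer(window_width))
  list(calls = calls, truth = truth)
}

# enumerate all cytosines and assign base (tissue/time-independent) p
.build_sites <- function(genome, cfg) {
  parts <- lapply(names(genome$seqs), function(ch) {
    dt <- .enumerate_cytosines(as.character(genome$seqs[[ch]]))
    dt[, chrom := ch]
    dt
  })
  sites <- data.table::rbindlist(parts)
  data.table::setcolorder(sites, c("chrom", "pos", "strand", "context"))
  data.table::setorder(sites, chrom, pos, strand)

  bl <- cfg$base_levels
  sites[, p_base := bl[as.character(context)]]
  for (ctx in c("CG", "CHG")) {
    mx <- .MIX[[ctx]]
    w <- min(1, max(0, (bl[[ctx]] - mx[["lo"]]) / (mx[["hi"]] - mx[["lo"]])))
    ii <- which(sites$context == ctx)
    hi <- runif(length(ii)) < w
    data.table::set(sites, ii, "p_base",
                    ifelse(hi, mx[["hi"]], mx[["lo"]]))
  }

  sites[, in_te := FALSE]
  if (nrow(genome$tes) > 0L) {
    te <- genome$tes[, .(chrom, start, end)]
    data.table::setkey(te, chrom, start, end)
    hit <- data.table::foverlaps(
      sites[, .(chrom, start = pos - 1L, end = pos)], te,
      type = "any", nomatch = NULL, which = TRUE)
    sites[unique(hit$xid), in_te := TRUE]
    sites[in_te == TRUE, p_base := pmin(1, p_base + cfg$te_boost)]
  }

  sites[chrom == genome$control_contig, p_base := 0]
  sites[, planted_id := NA_integer_]
  sites[]
}

# gene-level expression plan + planted DMR intervals (needs no counts)
.plan_truth <- function(genome, cfg) {
  genes <- data.table::copy(genome$genes)
  ng <- nrow(genes)
  genes[, u_gene := if (ng) runif(ng) else numeric(0)]
  genes[, silent := u_gene > 0.85]
  genes[, base_mean := rlnorm(ng, meanlog = log(cfg$mean_expression),
                              sdlog = 1.2) *
          2^(-cfg$expr_meth_log2_slope * u_gene)]
  genes[silent == TRUE, base_mean := 0.02]
  genes[, de := FALSE]
  genes[, de_sign := 0L]
  genes[, linked := FALSE]

  n_de <- min(cfg$n_de_genes, ng)
  if (n_de > 0L) {
    eligible <- genes[silent == FALSE & base_mean >= 10, gene_id]
    if (length(eligible) < n_de) {
      extra <- genes[!gene_id %in% eligible][order(-base_mean), gene_id]
      eligible <- c(eligible, extra[seq_len(n_de - length(eligible))])
    }
    de_ids <- sample(eligible, n_de)
    genes[gene_id %in% de_ids, de := TRUE]
    # balanced up/down split keeps median-of-ratios normalisation unbiased
    genes[de == TRUE, de_sign := sample(rep_len(c(1L, -1L), .N))]
    k <- round(cfg$frac_dmr_linked_degs * n_de)
    linked_ids <- sample(de_ids, k)
    genes[gene_id %in% linked_ids, linked := TRUE]
  }

  planted <- .place_planted(genome, genes, cfg)
  list(genes = genes[], planted = planted)
}

# place planted intervals: tissue-contrast DMRs inside linked-gene envelopes,
# then diel DMRs per context anywhere else; all grid-aligned, non-overlapping
.place_planted <- function(genome, genes, cfg) {
  seqlens <- genome$seqlens
  rows <- list()
  taken <- list()  # per chrom IRanges of planted intervals
  add_taken <- function(ch, s, e) {
    ir <- IRanges::IRanges(s + 1L, e)
    taken[[ch]] <<- if (is.null(taken[[ch]])) ir else c(taken[[ch]], ir)
  }
  free <- function(ch, s, e) {
    is.null(taken[[ch]]) ||
      IRanges::countOverlaps(IRanges::IRanges(s + 1L, e), taken[[ch]]) == 0L
  }

  # tissue-contrast DMRs for DMR-linked DE genes
  lg <- genes[linked == TRUE]
  ctx_probs <- c(CG = 0.15, CHG = 0.25, CHH = 0.60)  # CHH-heavy context mix
  if (nrow(lg) > 0L) {
    for (i in seq_len(nrow(lg))) {
      len <- cfg$linked_dmr_length
      ch <- lg$chrom[i]
      env_s <- max(0L, lg$start[i] - 2000L)
      env_e <- min(seqlens[[ch]], lg$end[i] + 2000L)
      lo <- as.integer(ceiling(env_s / 100) * 100)
      hi <- as.integer(floor((env_e - len) / 100) * 100)
      if (hi < lo) next
      placed <- 0L; tries <- 0L
      while (placed < cfg$linked_dmrs_per_gene && tries < 50L) {
        tries <- tries + 1L
        s <- sample(seq(lo, hi, by = 100L), 1L)
        if (!free(ch, s, s + len)) next
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = ch, start = s, end = s + len,
          context = sample(.CONTEXTS, 1L, prob = ctx_probs),
          kind = "tissue", direction = sample(c(1L, -1L), 1L),
          gene_id = lg$gene_id[i])
        add_taken(ch, s, s + len)
        placed <- placed + 1L
      }
    }
  }

  # diel DMRs per context
  chroms <- setdiff(names(seqlens), genome$control_contig)
  for (ctx in .CONTEXTS) {
    n_want <- cfg$n_planted_dmrs[[ctx]]
    placed <- 0L; tries <- 0L
    while (placed < n_want) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_want))
        stop("chrom_len too small to place planted DMRs", call. = FALSE)
      ch <- sample(chroms, 1L)
      len <- cfg$dmr_length
      hi <- as.integer(floor((seqlens[[ch]] - len) / 100) * 100)
      s <- sample(seq(0L, hi, by = 100L), 1L)
      if (!free(ch, s, s + len)) next
      dir <- if (ctx == "CHH") 1L else sample(c(1L, -1L), 1L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = ch, start = s, end = s + len, context = ctx,
        kind = "diel", direction = dir, gene_id = NA_character_)
      add_taken(ch, s, s + len)
      placed <- placed + 1L
    }
  }

  planted <- data.table::rbindlist(rows)
  if (nrow(planted)) planted[, planted_id := seq_len(.N)]
  else planted <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    context = character(), kind = character(), direction = integer(),
    gene_id = character(), planted_id = integer())
  data.table::setcolorder(planted, c("planted_id", "chrom", "start", "end",
                                     "context", "kind", "direction", "gene_id"))
  planted[]
}

# mark sites inside planted intervals (context-matched) and reset their base
.apply_planted <- function(sites, planted, cfg) {
  if (nrow(planted) == 0L) return(sites)
  pl <- planted[, .(chrom, start, end, planted_id, pctx = context)]
  data.table::setkey(pl, chrom, start, end)
  q <- sites[, .(chrom, start = pos - 1L, end = pos)]
  ov <- data.table::foverlaps(q, pl, type = "any", nomatch = NULL, which = TRUE)
  if (nrow(ov)) {
    match_ctx <- as.character(sites$context[ov$xid]) == pl$pctx[ov$yid]
    ov <- ov[match_ctx]
    data.table::set(sites, ov$xid, "planted_id", pl$planted_id[ov$yid])
    bl <- cfg$base_levels
    data.table::set(sites, ov$xid, "p_base",
                    bl[as.character(sites$context[ov$xid])])
  }
  sites
}

# additive non-CG promoter methylation tied to each gene's repression u
.apply_promoter_boost <- function(sites, genome, genes, cfg) {
  if (nrow(genes) == 0L || cfg$promoter_meth_range == 0) return(sites)
  up <- .gene_flanks(genome$genes, genome$seqlens, 2000L)$upstream
  up <- merge(up, genes[, .(gene_id, u_gene)], by = "gene_id")
  up <- up[end > start, .(chrom, start, end, u_gene)]
  data.table::setkey(up, chrom, start, end)
  q <- sites[, .(chrom, start = pos - 1L, end = pos)]
  ov <- data.table::foverlaps(q, up, type = "any", nomatch = NULL, which = TRUE)
  if (nrow(ov)) {
    keep <- sites$context[ov$xid] != "CG" & is.na(sites$planted_id[ov$xid])
    ov <- ov[keep]
    boost <- cfg$promoter_meth_range * up$u_gene[ov$yid]
    data.table::set(sites, ov$xid, "p_base",
                    pmin(1, sites$p_base[ov$xid] + boost))
  }
  sites
}

# true methylation probability of every site in one tissue/time group
.site_group_p <- function(sites, planted, tissue, time, cfg) {
  p <- sites$p_base
  open_chh <- sites$context == "CHH" & is.na(sites$planted_id) & p > 0
  if (tissue == "white")
    p[open_chh] <- p[open_chh] - cfg$tissue_chh_delta
  else
    p[open_chh] <- p[open_chh] + cfg$diel_chh_amplitude * .diel_sign(time)
  pid <- sites$planted_id
  has <- which(!is.na(pid))
  if (length(has) && nrow(planted)) {
    dir <- planted$direction[pid[has]]
    kind <- planted$kind[pid[has]]
    eff <- cfg$planted_effect[as.character(sites$context[has])]
    on <- (kind == "tissue" & ((dir > 0) == (tissue == "green"))) |
      (kind == "diel" & tissue == "green" & .diel_sign(time) > 0)
    # tissue DMRs: effect added to the hypermethylated tissue at all times;
    # diel DMRs: signed effect added in green at 4pm/10pm only
    add <- ifelse(kind == "tissue", eff, eff * dir)
    p[has] <- p[has] + ifelse(on, add, 0)
  }
  pmin(1, pmax(0, p))
}

# noise-free window-level truth per group
.window_truth <- function(sites, group_p, window_width) {
  base <- sites[, .(chrom, pos, context)]
  base[, start := ((pos - 1L) %/% window_width) * window_width]
  parts <- lapply(names(group_p), function(g) {
    base[, p_true := group_p[[g]]]
    out <- base[, .(p_true = mean(p_true), n_sites = .N),
                by = .(chrom, start, context)]
    out[, group := g]
    out
  })
  wt <- data.table::rbindlist(parts)
  wt[, end := start + window_width]
  data.table::setcolorder(wt, c("group", "chrom", "start", "end", "context",
                                "p_true", "n_sites"))
  data.table::setorder(wt, group, chrom, start, context)
  wt[]
}
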