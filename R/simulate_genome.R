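#' Simulate a genome with gene models, TEs and a control contig
#'
#' Generates random chromosome sequences, places non-overlapping gene models
#' (each with at least one exon) along each chromosome with enough spacing
#' that their 2-kb flanking envelopes stay disjoint, places transposable
#' elements preferentially in the central "pericentromeric" fraction of each
#' chromosome (avoiding gene bodies), and appends one extra unmethylated
#' control contig emulating the chloroplast.
#'
#' @param cfg a [sim_config()].
#' @return a [GenomeModel].
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  L <- as.integer(cfg$chrom_len)

  seqs <- vapply(seq_len(cfg$n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  ctrl <- paste(sample(c("A", "C", "G", "T"), as.integer(cfg$control_len),
                       replace = TRUE), collapse = "")
  dss <- Biostrings::DNAStringSet(c(setNames(seqs, chroms), chrC = ctrl))

  peri <- data.table::data.table(
    chrom = chroms,
    start = as.integer(floor(L * (0.5 - cfg$pericentromere_fraction / 2))),
    end = as.integer(ceiling(L * (0.5 + cfg$pericentromere_fraction / 2))))

  # --- genes: sequential placement with gaps >= 5 kb (disjoint 2-kb envelopes)
  genes_per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chrom + 1)))
  min_gap <- 5000L
  gene_list <- vector("list", cfg$n_chrom)
  for (ci in seq_len(cfg$n_chrom)) {
    ng <- genes_per_chrom[ci]
    if (ng == 0L) { gene_list[[ci]] <- empty_genes(); next }
    lens <- as.integer(sample(1000:3000, ng, replace = TRUE))
    need <- sum(lens) + (ng + 1L) * min_gap
    if (need > L)
      stop("chrom_len too small to place requested genes/TEs", call. = FALSE)
    slack <- L - need
    # distribute the slack over the ng+1 gaps by a random stick-breaking
    cuts <- sort(sample.int(slack + 1L, ng, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))
    starts <- integer(ng); at <- 0L
    for (k in seq_len(ng)) {
      at <- at + min_gap + extra[k]
      starts[k] <- at
      at <- at + lens[k]
    }
    gene_list[[ci]] <- data.table::data.table(
      gene_id = sprintf("g%s_%03d", ci, seq_len(ng)),
      chrom = chroms[ci], start = starts, end = starts + lens,
      strand = sample(c("+", "-"), ng, replace = TRUE))
  }
  genes <- data.table::rbindlist(gene_list)

  # --- exons: partition each gene into exon/intron segments (>=1 exon)
  exons <- if (nrow(genes) == 0L) empty_genes() else genes[, {
    len <- end - start
    n_ex <- sample(1:4, 1L)
    if (n_ex == 1L) list(start = start, end = end) else {
      n_seg <- 2L * n_ex - 1L
      bks <- sort(sample(seq_len(len - 1L), n_seg - 1L))
      s <- start + c(0L, bks); e <- start + c(bks, len)
      keep <- seq(1L, n_seg, by = 2L)   # odd segments are exons
      list(start = s[keep], end = e[keep])
    }
  }, by = .(gene_id, chrom, strand)]
  data.table::setcolorder(exons, c("gene_id", "chrom", "start", "end", "strand"))

  # --- TEs: mostly inside the pericentromere, never overlapping gene bodies
  te_list <- vector("list", cfg$n_chrom)
  tes_per_chrom <- diff(round(seq(0, cfg$n_tes, length.out = cfg$n_chrom + 1)))
  for (ci in seq_len(cfg$n_chrom)) {
    nt <- tes_per_chrom[ci]
    if (nt == 0L) {
      te_list[[ci]] <- data.table::data.table(
        te_id = character(), chrom = character(),
        start = integer(), end = integer())
      next
    }
    g <- genes[chrom == chroms[ci]]
    occupied <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    p0 <- peri[chrom == chroms[ci]]
    placed_s <- integer(0); placed_e <- integer(0)
    tries <- 0L
    while (length(placed_s) < nt) {
      tries <- tries + 1L
      if (tries > 50L * nt)
        stop("chrom_len too small to place requested genes/TEs", call. = FALSE)
      w <- sample(300:3000, 1L)
      s <- if (runif(1) < 0.85)
        sample(seq(p0$start, max(p0$start, p0$end - w)), 1L)
      else sample(seq(0L, L - w), 1L)
      cand <- IRanges::IRanges(s + 1L, s + w)
      prev <- IRanges::IRanges(placed_s + 1L, placed_e)
      if (IRanges::countOverlaps(cand, occupied) == 0L &&
          (length(prev) == 0L || IRanges::countOverlaps(cand, prev) == 0L)) {
        placed_s <- c(placed_s, s); placed_e <- c(placed_e, s + w)
      }
    }
    o <- order(placed_s)
    te_list[[ci]] <- data.table::data.table(
      te_id = sprintf("te%s_%03d", ci, seq_len(nt)),
      chrom = chroms[ci], start = placed_s[o], end = placed_e[o])
  }
  tes <- data.table::rbindlist(te_list)

  GenomeModel(seqs = dss, genes = genes, exons = exons, tes = tes,
              control_contig = "chrC", pericentromere = peri)
}
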