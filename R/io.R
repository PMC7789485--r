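# Standard-format I/O.
#
# Coordinates: 1-based closed in GFF3 and CX reports; 0-based half-open in
# BED. Internal tables are 0-based half-open.

#' Write / read genome FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param path file path.
#' @return `write_fasta`: the path, invisibly; `read_fasta`: a DNAStringSet.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  s
}

#' Write / read the study annotation as GFF3
#'
#' Features: `gene`, `exon` (with `Parent`), `transposable_element`.
#' Written via rtracklayer; `read_gff3` reconstructs the gene/exon/TE tables
#' of a [GenomeModel] (0-based half-open internally).
#'
#' @param genome a [GenomeModel].
#' @param path file path.
#' @param seqs sequences to attach on read (optional; default builds a
#'   sequence-less model with lengths inferred from the file is not
#'   possible, so pass `seqs` for a full model).
#' @return `write_gff3`: the path, invisibly; `read_gff3`: a list with
#'   `genes`, `exons`, `tes` data.tables (and a [GenomeModel] when `seqs`
#'   is given).
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes; e <- genome$exons; t <- genome$tes
  mk <- function(dt, type, id, parent = NA_character_) {
    if (nrow(dt) == 0L) return(NULL)
    gr <- GenomicRanges::GRanges(
      seqnames = dt$chrom,
      ranges = IRanges::IRanges(dt$start + 1L, dt$end),
      strand = if ("strand" %in% names(dt)) dt$strand else "*")
    gr$type <- type
    gr$ID <- id
    gr$Parent <- parent
    gr
  }
  all <- do.call(c, Filter(Negate(is.null), list(
    mk(g, "gene", g$gene_id),
    {
      if (nrow(e)) {
        eo <- data.table::copy(e)
        eo[, idx := seq_len(.N), by = gene_id]
        mk(eo, "exon", sprintf("%s.exon%d", eo$gene_id, eo$idx), eo$gene_id)
      } else NULL
    },
    mk(t, "transposable_element", t$te_id))))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path, seqs = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- names(S4Vectors::mcols(gr))
  parent <- if ("Parent" %in% mc)
    vapply(as.list(gr$Parent), function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
  else rep(NA_character_, length(gr))
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    ID = if ("ID" %in% mc) as.character(gr$ID) else NA_character_,
    Parent = parent)
  genes <- dt[type == "gene",
              .(gene_id = ID, chrom, start, end, strand)]
  exons <- dt[type == "exon",
              .(gene_id = Parent, chrom, start, end, strand)]
  tes <- dt[type == "transposable_element",
            .(te_id = ID, chrom, start, end)]
  data.table::setorder(genes, chrom, start)
  data.table::setorder(exons, gene_id, start)
  data.table::setorder(tes, chrom, start)
  out <- list(genes = genes[], exons = exons[], tes = tes[])
  if (!is.null(seqs))
    out$genome <- GenomeModel(seqs, genes, exons, tes,
                              control_contig = setdiff(names(seqs),
                                                       unique(genes$chrom))[1])
  out
}

#' Write / read DMRs as BED6+
#'
#' BED columns: chrom, start, end (0-based half-open), name
#' (`context:direction`), score (`-10 log10 q`, capped at 1000), strand
#' (`.`), plus the full statistics columns. `read_bed` restores the DMR
#' table.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param path file path.
#' @return `write_bed`: the path, invisibly; `read_bed`: a DMR-like
#'   data.table.
#' @export
write_bed <- function(dmrs, path) {
  out <- dmrs[, .(chrom, start, end,
                  name = paste(context, direction, sep = ":"),
                  score = round(pmin(1000, -10 * log10(pmax(q_value, 1e-100))),
                                2),
                  strand = ".",
                  m_a, m_b, delta, p_value, q_value, n_cytosines,
                  meth_a, total_a, meth_b, total_b,
                  comparison_a, comparison_b)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  dt[, c("context", "direction") := data.table::tstrsplit(name, ":")]
  dt[, c("name", "score", "strand") := NULL]
  data.table::setcolorder(dt, c("chrom", "start", "end", "context",
                                "m_a", "m_b", "delta", "direction",
                                "p_value", "q_value", "n_cytosines",
                                "meth_a", "total_a", "meth_b", "total_b",
                                "comparison_a", "comparison_b"))
  dt[]
}

#' Write a WindowTable as per-context bedGraph files
#'
#' One bedGraph per context, skipping windows with undefined levels.
#'
#' @param windows a WindowTable.
#' @param prefix output path prefix; files are `<prefix>.<context>.bedGraph`.
#' @return character vector of written paths, invisibly.
#' @export
write_bedgraph <- function(windows, prefix) {
  paths <- vapply(.CONTEXTS, function(ctx) {
    p <- sprintf("%s.%s.bedGraph", prefix, ctx)
    sub <- windows[windows$context == ctx & !is.na(windows$m),
                   .(chrom, start, end, m)]
    data.table::fwrite(sub, p, sep = "\t", col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
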