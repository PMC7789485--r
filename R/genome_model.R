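#' Genome model: sequences, gene models, TEs, control contig
#'
#' Lightweight container tying together chromosome sequences, gene models
#' (gene spans + exons, from which introns are derived), transposable-element
#' intervals, the pericentromere layout and the identifier of the
#' unmethylated control contig used for conversion-rate QC.
#'
#' All interval tables use 0-based half-open coordinates internally; 1-based
#' closed coordinates appear only in GFF3/CX-report files.
#'
#' @param seqs a [Biostrings::DNAStringSet] of chromosome sequences.
#' @param genes data.table with columns `gene_id, chrom, start, end, strand`.
#' @param exons data.table with columns `gene_id, chrom, start, end, strand`.
#' @param tes data.table with columns `te_id, chrom, start, end`.
#' @param control_contig name of the unmethylated control contig (or NA).
#' @param pericentromere data.table `chrom, start, end` of TE-enriched cores.
#' @return an object of class `GenomeModel`.
#' @export
GenomeModel <- function(seqs,
                        genes = empty_genes(),
                        exons = empty_genes(),
                        tes = data.table::data.table(
                          te_id = character(), chrom = character(),
                          start = integer(), end = integer()),
                        control_contig = NA_character_,
                        pericentromere = NULL) {
  .assert(methods::is(seqs, "DNAStringSet"), "seqs must be a DNAStringSet")
  gm <- list(seqs = seqs,
             genes = data.table::as.data.table(genes),
             exons = data.table::as.data.table(exons),
             tes = data.table::as.data.table(tes),
             control_contig = control_contig,
             pericentromere = pericentromere,
             seqlens = setNames(Biostrings::width(seqs), names(seqs)))
  class(gm) <- "GenomeModel"
  gm
}

empty_genes <- function() {
  data.table::data.table(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character())
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf(
    "<GenomeModel> %d sequence(s), %s bp total; %d genes, %d TEs; control: %s\n",
    length(x$seqs), format(sum(x$seqlens), big.mark = ","),
    nrow(x$genes), nrow(x$tes), x$control_contig))
  invisible(x)
}

#' Intron intervals derived from gene models
#'
#' Introns are the gene-body intervals not covered by any exon of the gene.
#'
#' @param genome a [GenomeModel].
#' @return data.table `gene_id, chrom, start, end, strand` (0-based half-open).
#' @export
derive_introns <- function(genome) {
  ex <- genome$exons
  if (nrow(ex) == 0L) return(empty_genes())
  ex <- ex[order(gene_id, start)]
  out <- ex[, {
    if (.N <= 1L) list(start = integer(0), end = integer(0))
    else list(start = end[-.N], end = start[-1L])
  }, by = .(gene_id, chrom, strand)]
  out <- out[end > start]
  data.table::setcolorder(out, c("gene_id", "chrom", "start", "end", "strand"))
  out[]
}

# strand-aware flanks, truncated at chromosome bounds (0-based half-open)
.gene_flanks <- function(genes, seqlens, flank = 2000L) {
  g <- data.table::copy(genes)
  L <- seqlens[g$chrom]
  up <- g[, .(gene_id, chrom, strand)]
  up[, `:=`(start = ifelse(g$strand == "+", pmax(0L, g$start - flank), g$end),
            end = ifelse(g$strand == "+", g$start, pmin(L, g$end + flank)))]
  dn <- g[, .(gene_id, chrom, strand)]
  dn[, `:=`(start = ifelse(g$strand == "+", g$end, pmax(0L, g$start - flank)),
            end = ifelse(g$strand == "+", pmin(L, g$end + flank), g$start))]
  up[, truncated := (end - start) < flank]
  dn[, truncated := (end - start) < flank]
  list(upstream = up[], downstream = dn[])
}
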