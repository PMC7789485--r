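# Cytosine sequence-context classification (CG / CHG / CHH, H = A, T or C).
#
# Plus-strand cytosines are classified from the two downstream bases; minus
# strand cytosines (genomic G) from the two upstream bases, complemented.
# Cytosines with fewer than two downstream bases on their own strand get the
# deterministic CHH-by-convention label.

#' Classify the sequence context of a position
#'
#' Returns the methylation context of the cytosine at `pos` on `strand`
#' of `chrom`, reading the reference sequence of a [GenomeModel]. Positions
#' that do not carry a cytosine on the requested strand return
#' `"not-a-cytosine"`. Cytosines with a truncated downstream context
#' (within 2 bp of the 3' contig end on their strand) are classified CHH by
#' convention.
#'
#' @param genome a [GenomeModel].
#' @param chrom chromosome identifier.
#' @param pos 1-based position (vectorised).
#' @param strand `"+"` or `"-"` (vectorised, recycled).
#' @return character vector in `c("CG","CHG","CHH","not-a-cytosine")`.
#' @export
#' @examples
#' g <- GenomeModel(seqs = Biostrings::DNAStringSet(c(chr1 = "ACGTA")))
#' classify_context(g, "chr1", 2, "+")  # CG
classify_context <- function(genome, chrom, pos, strand = "+") {
  .assert(inherits(genome, "GenomeModel"), "genome must be a GenomeModel")
  .assert(length(chrom) == 1L, "one chromosome at a time")
  if (!chrom %in% names(genome$seqs))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  seq <- as.character(genome$seqs[[chrom]])
  L <- nchar(seq)
  .assert(all(pos >= 1 & pos <= L), "pos outside chromosome")
  b <- charToRaw(seq)
  n <- max(length(pos), length(strand))
  pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  out <- character(n)
  C <- charToRaw("C"); G <- charToRaw("G")
  for (i in seq_len(n)) {
    p <- pos[i]
    if (strand[i] == "+") {
      if (b[p] != C) { out[i] <- "not-a-cytosine"; next }
      if (p > L - 2L) { out[i] <- "CHH"; next }          # truncated 3' context
      out[i] <- if (b[p + 1L] == G) "CG"
                else if (b[p + 2L] == G) "CHG" else "CHH"
    } else {
      if (b[p] != G) { out[i] <- "not-a-cytosine"; next }
      if (p < 3L) { out[i] <- "CHH"; next }
      out[i] <- if (b[p - 1L] == C) "CG"
                else if (b[p - 2L] == C) "CHG" else "CHH"
    }
  }
  out
}

# Vectorised enumeration of every cytosine (both strands) of one sequence.
# Returns data.table(pos, strand, context); pos 1-based.
.enumerate_cytosines <- function(seq_string) {
  b <- charToRaw(seq_string)
  L <- length(b)
  C <- charToRaw("C"); G <- charToRaw("G")
  isC <- b == C; isG <- b == G
  # plus strand
  pp <- which(isC)
  nxt1 <- c(isG[-1L], FALSE)        # base at p+1 is G
  nxt2 <- c(isG[-(1:2)], FALSE, FALSE)
  ctx_p <- ifelse(nxt1[pp], "CG", ifelse(nxt2[pp], "CHG", "CHH"))
  ctx_p[pp > L - 2L] <- "CHH"   # truncated 3' context convention
  # minus strand (genomic G read as C); upstream bases complemented
  pm <- which(isG)
  prv1 <- c(FALSE, isC[-L])         # base at p-1 is C  -> CG
  prv2 <- c(FALSE, FALSE, isC[-((L - 1L):L)])
  ctx_m <- ifelse(prv1[pm], "CG", ifelse(prv2[pm], "CHG", "CHH"))
  ctx_m[pm < 3L] <- "CHH"
  data.table::data.table(
    pos = c(pp, pm),
    strand = rep(c("+", "-"), c(length(pp), length(pm))),
    context = factor(c(ctx_p, ctx_m), levels = .CONTEXTS)
  )
}
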