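# Cytosine call sets: ingestion, pooling and QC.
#
# A call set is a data.table with columns
#   chrom, pos (1-based), strand (+/-), context (CG/CHG/CHH),
#   n_meth, n_total
# and one record per (chrom, pos, strand).

#' Validate a cytosine call set
#'
#' Checks column presence, count sanity (`0 <= n_meth <= n_total`) and
#' record uniqueness per (chrom, pos, strand).
#'
#' @param calls a call-set data.table.
#' @return the call set, invisibly.
#' @export
validate_calls <- function(calls) {
  need <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  .assert(all(need %in% names(calls)),
          paste("call set must have columns:", paste(need, collapse = ", ")))
  .assert(all(calls$n_meth >= 0 & calls$n_meth <= calls$n_total),
          "need 0 <= n_meth <= n_total")
  .assert(!anyDuplicated(calls, by = c("chrom", "pos", "strand")),
          "duplicate (chrom, pos, strand) records")
  invisible(calls)
}

#' Pool replicate call sets by summing counts per cytosine
#'
#' @param call_list list of call-set data.tables on the same cytosine space.
#' @return a pooled call set.
#' @export
pool_calls <- function(call_list) {
  .assert(length(call_list) >= 1L, "need at least one call set")
  all <- data.table::rbindlist(call_list)
  out <- all[, .(n_meth = sum(n_meth), n_total = sum(n_total)),
             by = .(chrom, pos, strand, context)]
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Merge symmetric CpG strand pairs
#'
#' Optionally combines each CG dinucleotide's two strand records (plus-strand
#' C at position p, minus-strand C at p + 1) into one record at the
#' plus-strand position with summed counts. Per-strand records are the
#' package default (merging changes denominators); this is the explicit
#' opt-in. Non-CG records pass through unchanged.
#'
#' @param calls a call set.
#' @return a call set in which complete CG pairs are merged (strand `"+"`).
#' @export
merge_cg_strands <- function(calls) {
  cg <- calls[context == "CG"]
  rest <- calls[context != "CG"]
  plus <- cg[strand == "+"]
  minus <- cg[strand == "-"][, .(chrom, pos = pos - 1L,
                                 m2 = n_meth, t2 = n_total)]
  merged <- merge(plus, minus, by = c("chrom", "pos"), all.x = TRUE)
  merged[!is.na(t2), `:=`(n_meth = n_meth + m2, n_total = n_total + t2)]
  merged[, c("m2", "t2") := NULL]
  # minus-strand CGs with no plus partner (contig-edge cases) kept as-is
  paired <- merged[, paste(chrom, pos + 1L)]
  orphan <- cg[strand == "-"][!paste(chrom, pos) %in% paired]
  out <- data.table::rbindlist(list(rest, merged, orphan), use.names = TRUE)
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Bisulfite conversion rate from an unmethylated control contig
#'
#' One minus the weighted methylation level (all contexts pooled) over the
#' control contig, following the chloroplast-based QC convention.
#'
#' @param calls a call set.
#' @param control_contig control contig name.
#' @return conversion rate in `[0, 1]`; `NA` (with a warning) if the control
#'   contig has no covered cytosine.
#' @export
conversion_rate <- function(calls, control_contig) {
  ctrl <- calls[chrom == control_contig]
  .assert(nrow(ctrl) > 0L, paste("control contig not present:", control_contig))
  tot <- sum(as.numeric(ctrl$n_total))
  if (tot == 0) {
    warning("conversion rate undefined: zero coverage on control contig (QC failure)")
    return(NA_real_)
  }
  1 - sum(as.numeric(ctrl$n_meth)) / tot
}

#' Filter cytosines by minimum read coverage
#'
#' @param calls a call set.
#' @param min_reads minimum `n_total` to retain (default 4, the
#'   covered-by-at-least-four-reads convention).
#' @return list with `calls` (retained records) and `coverage_fraction`
#'   (fraction of input cytosines retained).
#' @export
coverage_filter <- function(calls, min_reads = 4L) {
  kept <- calls[n_total >= min_reads]
  list(calls = kept,
       coverage_fraction = if (nrow(calls)) nrow(kept) / nrow(calls)
                           else NA_real_)
}

#' Write / read a CX-report-style per-cytosine TSV
#'
#' Columns: chrom, pos (1-based), strand, context, count_methylated,
#' count_unmethylated. `read_cx` converts back to the internal call-set
#' layout (`n_meth`, `n_total`).
#'
#' @param calls a call set.
#' @param path file path.
#' @return `write_cx`: the path, invisibly. `read_cx`: a call set.
#' @export
write_cx <- function(calls, path) {
  out <- calls[, .(chrom, pos, strand, context = as.character(context),
                   count_methylated = n_meth,
                   count_unmethylated = n_total - n_meth)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_cx
#' @export
read_cx <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("chrom", "strand",
                                                          "context")))
  out <- dt[, .(chrom, pos = as.integer(pos), strand, context,
                n_meth = as.integer(count_methylated),
                n_total = as.integer(count_methylated + count_unmethylated))]
  validate_calls(out)
  out[]
}
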