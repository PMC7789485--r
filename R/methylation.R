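# Weighted methylation levels over regions and fixed windows.
#
# The weighted methylation level of a region is
#   sum(n_meth) / sum(n_total)
# over covered cytosines of the requested context: coverage-weighted, never
# a mean of per-site ratios. Zero denominators propagate as NA (missing),
# never as 0.

#' Weighted methylation level of a genomic region
#'
#' @param calls a call set.
#' @param chrom chromosome.
#' @param start,end region as 0-based half-open interval.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`, or `"all"` to pool
#'   contexts.
#' @return the level in `[0, 1]`, or `NA` when no covered cytosine of the
#'   context lies in the region.
#' @export
#' @examples
#' calls <- data.table::data.table(
#'   chrom = "chr1", pos = c(10L, 20L), strand = "+", context = "CG",
#'   n_meth = c(3L, 1L), n_total = c(10L, 10L))
#' weighted_methylation(calls, "chr1", 0, 100, "CG")  # 4/20 = 0.2
weighted_methylation <- function(calls, chrom, start, end, context = "all") {
  .assert(start < end, "invalid interval: start >= end")
  ch <- chrom; ctx <- context; s0 <- start; e0 <- end
  sub <- calls[calls$chrom == ch & calls$pos > s0 & calls$pos <= e0]
  if (ctx != "all") sub <- sub[sub$context == ctx]
  tot <- sum(as.numeric(sub$n_total))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(sub$n_meth)) / tot
}

# window start grid for one chromosome: tiling or sliding; the chromosome
# end is covered by at most one trailing partial window per family
.window_starts <- function(L, width, step) {
  if (L <= width) return(0)
  last <- ceiling((L - width) / step) * step
  seq(0, last, by = step)
}

#' Fixed-width genomic windows with per-context weighted methylation
#'
#' Tiles (step = width) or slides (step < width) windows along each
#' chromosome and computes, per window and context, the number of covered
#' cytosines, pooled counts and the weighted methylation level. The trailing
#' partial window is kept. Windows with no covered cytosine of a context
#' carry `NA` levels.
#'
#' @param calls a call set.
#' @param seqlens named vector of chromosome lengths (bp). Chromosomes
#'   absent from `calls` still produce (empty) windows.
#' @param width window width in bp (default 100).
#' @param step step between window starts (default `width`, i.e. tiling).
#' @return a WindowTable: data.table `chrom, start, end, context,
#'   n_cytosines, sum_meth, sum_total, m` with one row per window x context.
#' @export
make_windows <- function(calls, seqlens, width = 100L, step = width) {
  .assert(width > 0 && step > 0, "width and step must be positive")
  .assert(step <= width, "step must not exceed width")
  grid <- data.table::rbindlist(lapply(names(seqlens), function(ch) {
    s <- .window_starts(seqlens[[ch]], width, step)
    data.table::data.table(chrom = ch, start = as.integer(s),
                           end = as.integer(pmin(s + width, seqlens[[ch]])))
  }))
  grid <- grid[, data.table::CJ(context = .CONTEXTS, sorted = FALSE),
               by = .(chrom, start, end)]

  if (nrow(calls) == 0L) {
    agg <- data.table::data.table(chrom = character(), start = integer(),
                                  context = character(), n_cytosines = integer(),
                                  sum_meth = numeric(), sum_total = numeric())
  } else if (step == width) {
    cc <- calls[, .(chrom, pos, context = as.character(context),
                    n_meth, n_total)]
    cc[, start := as.integer(((pos - 1L) %/% width) * width)]
    # trailing partial window: clamp starts beyond the last grid start
    lastmap <- grid[, .(last = max(start)), by = chrom]
    cc <- lastmap[cc, on = "chrom"]
    cc[start > last, start := last]
    agg <- cc[, .(n_cytosines = sum(n_total > 0),
                  sum_meth = sum(as.numeric(n_meth)),
                  sum_total = sum(as.numeric(n_total))),
              by = .(chrom, start, context)]
  } else {
    win <- unique(grid[, .(chrom, start, end)])
    agg_parts <- lapply(split(seq_len(nrow(win)), win$chrom), function(ii) {
      w <- win[ii]
      ch <- w$chrom[1L]
      cc <- calls[calls$chrom == ch]
      if (nrow(cc) == 0L) return(NULL)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(w$start + 1L, w$end),
        IRanges::IRanges(cc$pos, cc$pos))
      dt <- data.table::data.table(
        chrom = ch,
        start = w$start[S4Vectors::queryHits(ov)],
        context = as.character(cc$context[S4Vectors::subjectHits(ov)]),
        n_meth = cc$n_meth[S4Vectors::subjectHits(ov)],
        n_total = cc$n_total[S4Vectors::subjectHits(ov)])
      dt[, .(n_cytosines = sum(n_total > 0),
             sum_meth = sum(as.numeric(n_meth)),
             sum_total = sum(as.numeric(n_total))),
         by = .(chrom, start, context)]
    })
    agg <- data.table::rbindlist(agg_parts)
  }

  out <- merge(grid, agg, by = c("chrom", "start", "context"), all.x = TRUE)
  out[is.na(n_cytosines), `:=`(n_cytosines = 0L, sum_meth = 0, sum_total = 0)]
  out[, m := ifelse(sum_total > 0, sum_meth / sum_total, NA_real_)]
  data.table::setcolorder(out, c("chrom", "start", "end", "context",
                                 "n_cytosines", "sum_meth", "sum_total", "m"))
  data.table::setorder(out, chrom, start, context)
  out[]
}

#' Pearson correlation of window methylation between two replicates
#'
#' Windows undefined (NA level) in either replicate are dropped pairwise.
#'
#' @param rep1,rep2 WindowTables from [make_windows()] on the same grid.
#' @param context context to correlate.
#' @return Pearson correlation coefficient; `NA` with fewer than 2 complete
#'   pairs.
#' @export
replicate_correlation <- function(rep1, rep2, context = "CG") {
  ctx <- context
  a <- rep1[rep1$context == ctx, .(chrom, start, m1 = m)]
  b <- rep2[rep2$context == ctx, .(chrom, start, m2 = m)]
  .assert(nrow(a) == nrow(b), "window grids differ between replicates")
  ab <- merge(a, b, by = c("chrom", "start"))
  .assert(nrow(ab) == nrow(a), "window grids differ between replicates")
  ok <- stats::complete.cases(ab[, .(m1, m2)])
  if (sum(ok) < 2L) return(NA_real_)
  cor(ab$m1[ok], ab$m2[ok])
}
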