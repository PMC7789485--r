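# Window-based differential methylation calling.
#
# A 100-bp window is a DMR between two sample groups iff
#   (i)  both groups have pooled coverage and >= min_cytosines covered
#        cytosines of the context,
#   (ii) a two-sided Fisher exact test on the pooled 2x2 count table is
#        significant after Benjamini-Hochberg adjustment (q <= alpha), and
#   (iii) the absolute weighted-methylation difference reaches the
#        context-specific threshold (0.4 CG / 0.2 CHG / 0.1 CHH).
# Direction is relative to the first-named group: hyper iff delta > 0.

#' Context-specific DMR effect-size thresholds
#' @export
dmr_thresholds <- function() c(CG = 0.4, CHG = 0.2, CHH = 0.1)

#' Two-sided Fisher exact test for 2x2 tables (vectorised)
#'
#' Conditional on fixed margins, sums hypergeometric probabilities of all
#' tables as or less likely than the observed one (the minimum-likelihood
#' two-sided convention, as in `stats::fisher.test`). Vectorised over
#' tables; tails are accumulated with `phyper` and the second-tail boundary
#' is located by bisection on the unimodal hypergeometric pmf.
#'
#' @param a,b,c_,d_ cell counts: table `[[a, b], [c_, d_]]`, i.e. rows are
#'   groups and columns are methylated / unmethylated.
#' @return vector of two-sided p-values; tables with an empty margin return
#'   1 by convention.
#' @export
#' @examples
#' fisher_exact(0, 10, 10, 0)           # 2 / choose(20, 10)
#' fisher_exact(5, 5, 5, 5)             # 1
fisher_exact <- function(a, b, c_, d_) {
  n <- max(length(a), length(b), length(c_), length(d_))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c_ <- rep_len(as.numeric(c_), n); d_ <- rep_len(as.numeric(d_), n)
  .assert(all(c(a, b, c_, d_) >= 0), "counts must be non-negative")
  N <- a + b + c_ + d_
  K <- a + b          # size of group 1 (white balls)
  NK <- c_ + d_
  m1 <- a + c_        # methylated margin (draws)
  p <- rep(1, n)
  ok <- K > 0 & NK > 0 & m1 > 0 & (b + d_) > 0
  if (!any(ok)) return(p)
  i <- which(ok)
  Ki <- K[i]; NKi <- NK[i]; mi <- m1[i]; ai <- a[i]
  lo <- pmax(0, mi - NKi); hi <- pmin(Ki, mi)
  eps <- 1 + 1e-7
  d0 <- dhyper(ai, Ki, NKi, mi) * eps
  mode <- floor((mi + 1) * (Ki + 1) / (Ki + NKi + 2))
  pv <- numeric(length(i))

  left <- ai <= mode   # observed on/left of the mode
  # own-side tail
  own <- ifelse(left, phyper(ai, Ki, NKi, mi),
                phyper(ai - 1, Ki, NKi, mi, lower.tail = FALSE))
  # opposite-side tail: find outermost x beyond the mode with pmf <= d0
  # left-observed -> search decreasing limb (mode..hi) for smallest such x;
  # right-observed -> search increasing limb (lo..mode) for largest such x
  oth <- numeric(length(i))
  il <- which(left)
  if (length(il)) {
    losrch <- pmax(mode[il], ai[il] + 1); hisrch <- hi[il] + 1
    repeat {
      act <- losrch < hisrch
      if (!any(act)) break
      mid <- (losrch + hisrch) %/% 2
      le <- dhyper(mid, Ki[il], NKi[il], mi[il]) <= d0[il]
      hisrch <- ifelse(act & le, mid, hisrch)
      losrch <- ifelse(act & !le, mid + 1, losrch)
    }
    oth[il] <- ifelse(losrch > hi[il], 0,
                      phyper(losrch - 1, Ki[il], NKi[il], mi[il],
                             lower.tail = FALSE))
  }
  ir <- which(!left)
  if (length(ir)) {
    losrch <- lo[ir] - 1; hisrch <- pmin(mode[ir], ai[ir] - 1)
    repeat {
      act <- losrch < hisrch
      if (!any(act)) break
      mid <- ceiling((losrch + hisrch) / 2)
      le <- dhyper(mid, Ki[ir], NKi[ir], mi[ir]) <= d0[ir]
      losrch <- ifelse(act & le, mid, losrch)
      hisrch <- ifelse(act & !le, mid - 1, hisrch)
    }
    oth[ir] <- ifelse(losrch < lo[ir], 0,
                      phyper(losrch, Ki[ir], NKi[ir], mi[ir]))
  }
  p[i] <- pmin(1, own + oth)
  p
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (wraps `stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  .assert(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call DMRs between two groups on aligned window tables
#'
#' @param windows_a,windows_b WindowTables from [make_windows()] on pooled
#'   replicate counts of each group, sharing the window grid.
#' @param context context to test (one of CG/CHG/CHH).
#' @param thresholds named vector of minimum `|delta m|` per context.
#' @param alpha BH-adjusted significance level.
#' @param min_cytosines minimum covered cytosines of the context per window
#'   in both groups.
#' @param comparison optional `c(groupA, groupB)` labels carried in output.
#' @return data.table of DMRecords: `chrom, start, end, context, m_a, m_b,
#'   delta, direction, p_value, q_value, n_cytosines, meth_a, total_a,
#'   meth_b, total_b, comparison_a, comparison_b`. Attribute `"n_tested"`
#'   holds the number of assessable windows.
#' @export
call_dmrs <- function(windows_a, windows_b, context,
                      thresholds = dmr_thresholds(), alpha = 0.05,
                      min_cytosines = 4L,
                      comparison = c("A", "B")) {
  ctx <- context
  .assert(ctx %in% .CONTEXTS, "context must be one of CG, CHG, CHH")
  wa <- windows_a[windows_a$context == ctx,
                  .(chrom, start, end, n_cyt_a = n_cytosines,
                    meth_a = sum_meth, total_a = sum_total, m_a = m)]
  wb <- windows_b[windows_b$context == ctx,
                  .(chrom, start, end, n_cyt_b = n_cytosines,
                    meth_b = sum_meth, total_b = sum_total, m_b = m)]
  .assert(nrow(wa) == nrow(wb), "mismatched window grids")
  w <- merge(wa, wb, by = c("chrom", "start", "end"))
  .assert(nrow(w) == nrow(wa), "mismatched window grids")

  w <- w[total_a > 0 & total_b > 0 &
           n_cyt_a >= min_cytosines & n_cyt_b >= min_cytosines]
  n_tested <- nrow(w)
  if (n_tested == 0L) {
    out <- w[, .(chrom, start, end)][0]
    out[, `:=`(context = character(), m_a = numeric(), m_b = numeric(),
               delta = numeric(), direction = character(),
               p_value = numeric(), q_value = numeric(),
               n_cytosines = integer(), meth_a = numeric(),
               total_a = numeric(), meth_b = numeric(), total_b = numeric(),
               comparison_a = character(), comparison_b = character())]
    data.table::setattr(out, "n_tested", 0L)
    return(out[])
  }
  w[, p_value := fisher_exact(meth_a, total_a - meth_a,
                              meth_b, total_b - meth_b)]
  w[, q_value := bh_adjust(p_value)]
  w[, delta := m_a - m_b]
  out <- w[q_value <= alpha & abs(delta) >= thresholds[[ctx]]]
  out[, `:=`(context = ctx,
             direction = ifelse(delta > 0, "hyper", "hypo"),
             n_cytosines = pmin(n_cyt_a, n_cyt_b),
             comparison_a = comparison[1L], comparison_b = comparison[2L])]
  out[, c("n_cyt_a", "n_cyt_b") := NULL]
  data.table::setcolorder(out, c("chrom", "start", "end", "context",
                                 "m_a", "m_b", "delta", "direction",
                                 "p_value", "q_value", "n_cytosines",
                                 "meth_a", "total_a", "meth_b", "total_b",
                                 "comparison_a", "comparison_b"))
  data.table::setorder(out, chrom, start)
  data.table::setattr(out, "n_tested", n_tested)
  out[]
}

#' Merge adjacent DMR windows and recompute pooled statistics
#'
#' Merges same-context, same-direction DMR windows whose gap is at most
#' `gap` bp into single regions, re-pooling counts and recomputing the
#' weighted levels, delta and Fisher p-value on the merged counts
#' (q-values are re-adjusted across the merged set). Window-level counting
#' is the default elsewhere; merging is an optional view.
#'
#' @param dmrs DMR table from [call_dmrs()] (one context).
#' @param gap maximum gap (bp) between windows to merge (0 = only
#'   book-ended windows).
#' @return a merged DMR table with an added `n_windows` column.
#' @export
merge_dmrs <- function(dmrs, gap = 0L) {
  if (nrow(dmrs) <= 1L) {
    out <- data.table::copy(dmrs)
    out[, n_windows := rep(1L, .N)]
    return(out[])
  }
  .assert(length(unique(dmrs$context)) == 1L, "merge one context at a time")
  d <- dmrs[order(chrom, start)]
  d[, run := cumsum(c(1L, (chrom[-1L] != chrom[-.N]) |
                        (start[-1L] - end[-.N] > gap) |
                        (direction[-1L] != direction[-.N])))]
  out <- d[, {
    ma <- sum(meth_a); ta <- sum(total_a)
    mb <- sum(meth_b); tb <- sum(total_b)
    m_a <- ma / ta; m_b <- mb / tb
    .(start = min(start), end = max(end), context = context[1L],
      m_a = m_a, m_b = m_b, delta = m_a - m_b, direction = direction[1L],
      p_value = fisher_exact(ma, ta - ma, mb, tb - mb),
      n_cytosines = sum(n_cytosines), meth_a = ma, total_a = ta,
      meth_b = mb, total_b = tb, comparison_a = comparison_a[1L],
      comparison_b = comparison_b[1L], n_windows = .N)
  }, by = .(chrom, run)]
  out[, run := NULL]
  out[, q_value := bh_adjust(p_value)]
  data.table::setcolorder(out, c("chrom", "start", "end", "context",
                                 "m_a", "m_b", "delta", "direction",
                                 "p_value", "q_value", "n_cytosines",
                                 "meth_a", "total_a", "meth_b", "total_b",
                                 "comparison_a", "comparison_b", "n_windows"))
  data.table::setorder(out, chrom, start)
  out[]
}

#' Classify DMRs into genomic feature classes
#'
#' Assigns each DMR exactly one class by maximal overlap, with precedence
#' promoter > exon > intron > downstream > intergenic on ties. Promoters are
#' the 2 kb upstream of the TSS; downstream regions the 2 kb past the 3'
#' end (both strand-aware).
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param genome a [GenomeModel].
#' @param flank promoter/downstream extent (default 2000).
#' @return `dmrs` with an added `feature_class` column.
#' @export
classify_dmr_features <- function(dmrs, genome, flank = 2000L) {
  out <- data.table::copy(dmrs)
  if (nrow(out) == 0L) { out[, feature_class := character(0)]; return(out[]) }
  fl <- .gene_flanks(genome$genes, genome$seqlens, flank)
  introns <- derive_introns(genome)
  classes <- data.table::rbindlist(list(
    fl$upstream[, .(chrom, start, end, klass = "promoter")],
    genome$exons[, .(chrom, start, end, klass = "exon")],
    if (nrow(introns)) introns[, .(chrom, start, end, klass = "intron")],
    fl$downstream[, .(chrom, start, end, klass = "downstream")]))
  classes <- classes[end > start]
  prec <- c(promoter = 1L, exon = 2L, intron = 3L, downstream = 4L)
  data.table::setkey(classes, chrom, start, end)
  q <- out[, .(chrom, start, end)]
  q[, xid := .I]
  ov <- data.table::foverlaps(q, classes, type = "any", nomatch = NULL)
  out[, feature_class := "intergenic"]
  if (nrow(ov)) {
    ov[, width_ov := pmin(i.end, end) - pmax(i.start, start)]
    ov[, prec_rank := prec[klass]]
    best <- ov[order(xid, -width_ov, prec_rank),
               .SD[1L], by = xid]
    out[best$xid, feature_class := best$klass]
  }
  out[]
}

#' Distribution of DMRs over feature classes
#'
#' @param dmrs output of [classify_dmr_features()].
#' @return data.table `feature_class, n, fraction`.
#' @export
dmr_feature_distribution <- function(dmrs) {
  lv <- c("promoter", "exon", "intron", "downstream", "intergenic")
  tb <- dmrs[, .(n = .N), by = feature_class]
  out <- merge(data.table::data.table(feature_class = lv), tb,
               by = "feature_class", all.x = TRUE, sort = FALSE)
  out[is.na(n), n := 0L]
  out[, fraction := if (sum(n) > 0) n / sum(n) else NA_real_]
  out[]
}

#' DMR state dynamics across successive diel comparisons
#'
#' For every window that is a DMR in at least one comparison, tabulates its
#' state (hyper / hypo / unchanged, relative to each comparison's first
#' group) and counts state-to-state transitions between successive
#' comparisons (the Sankey-plot analogue).
#'
#' @param dmr_list named list of DMR tables (same context, shared window
#'   grid), in chronological comparison order.
#' @return list with `states` (window x comparison state table) and
#'   `transitions` (data.table `step, from, to, n`; row sums over `to`
#'   equal the source-state counts).
#' @export
dmr_transitions <- function(dmr_list) {
  .assert(length(dmr_list) >= 2L, "need at least two comparisons")
  labs <- names(dmr_list) %||% paste0("cmp", seq_along(dmr_list))
  keys <- unique(data.table::rbindlist(
    lapply(dmr_list, function(d) d[, .(chrom, start, end)])))
  if (nrow(keys) == 0L)
    return(list(states = keys,
                transitions = data.table::data.table(
                  step = character(), from = character(), to = character(),
                  n = integer())))
  states <- data.table::copy(keys)
  for (j in seq_along(dmr_list)) {
    d <- dmr_list[[j]][, .(chrom, start, end, direction)]
    states <- merge(states, d, by = c("chrom", "start", "end"), all.x = TRUE)
    data.table::setnames(states, "direction", labs[j])
    states[is.na(get(labs[j])), (labs[j]) := "unchanged"]
  }
  trans <- data.table::rbindlist(lapply(seq_len(length(dmr_list) - 1L),
    function(j) {
      tb <- states[, .(n = .N), by = .(from = get(labs[j]),
                                       to = get(labs[j + 1L]))]
      tb[, step := paste(labs[j], labs[j + 1L], sep = " -> ")]
      tb
    }))
  data.table::setcolorder(trans, c("step", "from", "to", "n"))
  list(states = states[], transitions = trans[])
}

#' Per-context, per-comparison DMR summary
#'
#' Counts, hyper/hypo split and a histogram of methylation differences.
#'
#' @param dmr_list named list of DMR tables (possibly mixed contexts).
#' @param breaks histogram breaks on `|delta|` (default 0..1 by 0.05).
#' @return list with `counts` (data.table `comparison, context, n, n_hyper,
#'   n_hypo`) and `delta_hist` (data.table `comparison, context, bin_lo,
#'   bin_hi, n`).
#' @export
dmr_density_summary <- function(dmr_list, breaks = seq(0, 1, by = 0.05)) {
  labs <- names(dmr_list) %||% paste0("cmp", seq_along(dmr_list))
  all <- data.table::rbindlist(lapply(seq_along(dmr_list), function(j) {
    d <- data.table::copy(dmr_list[[j]])
    if (nrow(d)) d[, comparison := labs[j]]
    d
  }), fill = TRUE)
  if (nrow(all) == 0L)
    return(list(counts = data.table::data.table(
      comparison = character(), context = character(), n = integer(),
      n_hyper = integer(), n_hypo = integer()),
      delta_hist = data.table::data.table(
        comparison = character(), context = character(), bin_lo = numeric(),
        bin_hi = numeric(), n = integer())))
  counts <- all[, .(n = .N, n_hyper = sum(direction == "hyper"),
                    n_hypo = sum(direction == "hypo")),
                by = .(comparison, context)]
  all[, bin := cut(pmin(abs(delta), max(breaks)), breaks = breaks,
                   include.lowest = TRUE, right = FALSE)]
  hist <- all[, .(n = .N), by = .(comparison, context, bin)]
  hist[, `:=`(bin_lo = breaks[as.integer(bin)],
              bin_hi = breaks[as.integer(bin) + 1L])]
  hist[, bin := NULL]
  data.table::setcolorder(hist, c("comparison", "context", "bin_lo",
                                  "bin_hi", "n"))
  list(counts = counts[], delta_hist = hist[])
}
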