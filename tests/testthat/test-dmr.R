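# Fisher engine, BH adjustment, DMR calling, classification and dynamics.

test_that("fisher_exact matches closed forms and fisher.test", {
  expect_equal(fisher_exact(0, 10, 10, 0), 2 / choose(20, 10))
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(0, 0, 3, 7), 1)   # empty margin convention
  set.seed(17)
  for (i in 1:200) {
    t <- matrix(rpois(4, sample(c(1, 10, 80, 400), 1)), 2)
    expect_equal(fisher_exact(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_exact agrees with full enumeration on small-margin tables", {
  set.seed(23)
  for (i in 1:500) {
    tb <- as.integer(sample(0:15, 4, TRUE))
    p <- fisher_exact(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))   # monotone in sorted p
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

make_window_pair <- function(meth_a, total_a, meth_b, total_b, ncyt = 10L) {
  n <- length(meth_a)
  mk <- function(meth, total) data.table::data.table(
    chrom = "chr1", start = seq(0L, by = 100L, length.out = n),
    end = seq(100L, by = 100L, length.out = n), context = "CHH",
    n_cytosines = ncyt, sum_meth = meth, sum_total = total,
    m = ifelse(total > 0, meth / total, NA_real_))
  list(a = mk(meth_a, total_a), b = mk(meth_b, total_b))
}

test_that("call_dmrs applies the significance and effect-size rules", {
  # identical counts -> no DMR
  w <- make_window_pair(c(50, 10), c(200, 200), c(50, 10), c(200, 200))
  expect_identical(nrow(call_dmrs(w$a, w$b, "CHH")), 0L)
  # the CHH example: 100/200 vs 20/200 over 10 cytosines is a hyper DMR
  w <- make_window_pair(100, 200, 20, 200)
  d <- call_dmrs(w$a, w$b, "CHH")
  expect_identical(nrow(d), 1L)
  expect_identical(d$direction, "hyper")
  expect_equal(d$delta, 0.4)
  expect_lt(d$p_value, 1e-15)
  # CG at delta 0.35 with a tiny p is still not a DMR (threshold 0.4)
  w <- make_window_pair(550, 1000, 200, 1000)
  wa <- data.table::copy(w$a)[, context := "CG"]
  wb <- data.table::copy(w$b)[, context := "CG"]
  expect_identical(nrow(call_dmrs(wa, wb, "CG")), 0L)
  expect_gt(nrow(call_dmrs(wa, wb, "CG",
                           thresholds = c(CG = 0.3, CHG = 0.2, CHH = 0.1))),
            0L)
})

test_that("min_cytosines and missing windows make windows non-assessable", {
  w <- make_window_pair(100, 200, 20, 200, ncyt = 3L)
  d <- call_dmrs(w$a, w$b, "CHH", min_cytosines = 4L)
  expect_identical(nrow(d), 0L)
  expect_identical(attr(d, "n_tested"), 0L)
  w <- make_window_pair(c(100, 0), c(200, 0), c(20, 10), c(200, 100))
  d <- call_dmrs(w$a, w$b, "CHH")
  expect_identical(attr(d, "n_tested"), 1L)
})

test_that("swapping groups flips direction and negates delta", {
  set.seed(31)
  n <- 40
  ta <- rpois(n, 300) + 50; tb <- rpois(n, 300) + 50
  ma <- rbinom(n, ta, runif(n)); mb <- rbinom(n, tb, runif(n))
  w <- make_window_pair(ma, ta, mb, tb)
  d1 <- call_dmrs(w$a, w$b, "CHH", comparison = c("A", "B"))
  d2 <- call_dmrs(w$b, w$a, "CHH", comparison = c("B", "A"))
  expect_identical(nrow(d1), nrow(d2))
  m <- merge(d1[, .(chrom, start, delta, p_value)],
             d2[, .(chrom, start, delta2 = delta, p2 = p_value)],
             by = c("chrom", "start"))
  expect_equal(m$delta, -m$delta2)
  expect_equal(m$p_value, m$p2)
})

test_that("raising thresholds never increases the DMR count", {
  set.seed(37)
  n <- 60
  ta <- rpois(n, 400); tb <- rpois(n, 400)
  ma <- rbinom(n, ta, 0.5); mb <- rbinom(n, tb, runif(n, 0.1, 0.6))
  w <- make_window_pair(ma, ta, mb, tb)
  counts <- sapply(c(0.05, 0.1, 0.2, 0.4), function(th)
    nrow(call_dmrs(w$a, w$b, "CHH",
                   thresholds = c(CG = 0.4, CHG = 0.2, CHH = th))))
  expect_true(all(diff(counts) <= 0))
})

test_that("DMRs are classified by maximal overlap with promoter precedence", {
  genes <- data.table::data.table(gene_id = "g1", chrom = "chr1",
                                  start = 10000L, end = 13000L, strand = "+")
  exons <- data.table::data.table(
    gene_id = "g1", chrom = "chr1",
    start = c(10000L, 11500L), end = c(11000L, 13000L), strand = "+")
  g <- GenomeModel(Biostrings::DNAStringSet(
    c(chr1 = paste(rep("A", 20000), collapse = ""))),
    genes = genes, exons = exons)
  mk_dmr <- function(s, e) data.table::data.table(
    chrom = "chr1", start = s, end = e, context = "CHH", m_a = 0.5,
    m_b = 0.1, delta = 0.4, direction = "hyper", p_value = 1e-9,
    q_value = 1e-8, n_cytosines = 10L, meth_a = 100, total_a = 200,
    meth_b = 20, total_b = 200, comparison_a = "A", comparison_b = "B")
  # fully inside an exon
  expect_identical(classify_dmr_features(mk_dmr(10100L, 10200L), g)$feature_class,
                   "exon")
  # centred 1 kb upstream of the TSS -> promoter
  expect_identical(classify_dmr_features(mk_dmr(8950L, 9050L), g)$feature_class,
                   "promoter")
  # 60 bp intron + 40 bp exon -> intron by maximal overlap
  expect_identical(classify_dmr_features(mk_dmr(11440L, 11540L), g)$feature_class,
                   "intron")
  # far away -> intergenic
  expect_identical(classify_dmr_features(mk_dmr(18000L, 18100L), g)$feature_class,
                   "intergenic")
  # 2 kb past the 3' end -> downstream
  expect_identical(classify_dmr_features(mk_dmr(13500L, 13600L), g)$feature_class,
                   "downstream")
})

test_that("transition tables conserve window counts across the chain", {
  mk <- function(starts, dirs) data.table::data.table(
    chrom = "chr1", start = starts, end = starts + 100L,
    direction = dirs)
  d1 <- mk(c(0L, 100L), c("hyper", "hypo"))
  d2 <- mk(100L, "hyper")
  tr <- dmr_transitions(list(c1 = d1, c2 = d2))
  st <- tr$states
  expect_identical(nrow(st), 2L)
  # window hyper in comparison 1 only -> hyper -> unchanged
  expect_identical(st[start == 0L, c2], "unchanged")
  expect_identical(st[start == 100L, c1], "hypo")
  # row sums of the transition matrix equal source-state counts
  sums <- tr$transitions[, .(n = sum(n)), by = from]
  src <- st[, .(n = .N), by = .(from = c1)]
  expect_equal(sums[order(from)], src[order(from)])
})

test_that("an empty comparison set summarises to zero DMRs without error", {
  w <- make_window_pair(numeric(0), numeric(0), numeric(0), numeric(0))
  d <- call_dmrs(w$a, w$b, "CHH")
  s <- dmr_density_summary(list(x = d))
  expect_identical(nrow(s$counts), 0L)
})

test_that("merging adjacent DMR windows re-pools counts correctly", {
  set.seed(43)
  w <- make_window_pair(c(100, 110, 15), c(200, 210, 200),
                        c(20, 25, 14), c(200, 200, 200))
  d <- call_dmrs(w$a, w$b, "CHH")
  expect_identical(nrow(d), 2L)            # two adjacent hyper windows
  m <- merge_dmrs(d, gap = 0L)
  expect_identical(nrow(m), 1L)
  expect_identical(m$n_windows, 2L)
  expect_equal(m$meth_a, 210); expect_equal(m$total_a, 410)
  expect_equal(m$m_a, 210 / 410)
  expect_equal(m$p_value,
               fisher_exact(210, 410 - 210, 45, 400 - 45))
  # non-adjacent windows stay separate
  w2 <- make_window_pair(c(100, 15, 110), c(200, 200, 210),
                         c(20, 14, 25), c(200, 200, 200))
  d2 <- call_dmrs(w2$a, w2$b, "CHH")
  expect_identical(nrow(merge_dmrs(d2, gap = 0L)), 2L)
  expect_identical(nrow(merge_dmrs(d2, gap = 100L)), 1L)
})
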