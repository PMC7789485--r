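# Context classification, call-set QC and weighted methylation.

test_that("classify_context follows the tri-context definition on both strands", {
  g <- GenomeModel(seqs = Biostrings::DNAStringSet(c(chr1 = "ACGTA",
                                                     chr2 = "ACAGT")))
  expect_identical(classify_context(g, "chr1", 2, "+"), "CG")
  expect_identical(classify_context(g, "chr2", 2, "+"), "CHG")   # CAG
  # G at pos 3 of ACGTA reads as C on the minus strand, preceded by C -> CG
  expect_identical(classify_context(g, "chr1", 3, "-"), "CG")
  expect_identical(classify_context(g, "chr1", 1, "+"), "not-a-cytosine")
  # truncated 3' context -> CHH by convention
  g2 <- GenomeModel(seqs = Biostrings::DNAStringSet(c(c = "AACG")))
  expect_identical(classify_context(g2, "c", 3, "+"), "CHH")
  expect_error(classify_context(g, "nope", 1, "+"), "unknown chromosome")
})

test_that("vectorised cytosine enumeration agrees with per-position classification", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  g <- GenomeModel(seqs = Biostrings::DNAStringSet(c(chrX = s)))
  sites <- dielmeth:::.enumerate_cytosines(s)
  expect_gt(nrow(sites), 50)
  one_by_one <- mapply(function(p, st) classify_context(g, "chrX", p, st),
                       sites$pos, sites$strand)
  expect_identical(as.character(sites$context), unname(one_by_one))
})

test_that("conversion rate is one minus control-contig weighted methylation", {
  calls <- data.table::data.table(
    chrom = c("chrC", "chrC", "chr1"), pos = c(5L, 9L, 3L), strand = "+",
    context = "CHH", n_meth = c(13L, 0L, 50L), n_total = c(500L, 500L, 50L))
  expect_equal(conversion_rate(calls, "chrC"), 1 - 13 / 1000)
  calls0 <- data.table::copy(calls)[chrom == "chrC", n_meth := 0L]
  expect_equal(conversion_rate(calls0, "chrC"), 1)
  callsNA <- data.table::copy(calls)[chrom == "chrC", n_total := 0L]
  callsNA[chrom == "chrC", n_meth := 0L]
  expect_warning(r <- conversion_rate(callsNA, "chrC"), "QC failure")
  expect_true(is.na(r))
})

test_that("simulated control contig recovers the configured conversion error", {
  cfg <- tiny_cfg(seed = 33L, mean_coverage = 30, conversion_error = 0.01)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g, cfg)
  r <- conversion_rate(m$calls[[1]], "chrC")
  expect_gt(r, 0.985)  # 0.99 within binomial error at this depth
  expect_lt(r, 0.995)
})

test_that("coverage filter retains records at the threshold and reports the fraction", {
  calls <- random_calls(50)
  id <- coverage_filter(calls, min_reads = 0L)
  expect_identical(nrow(id$calls), nrow(calls))
  expect_equal(id$coverage_fraction, 1)
  calls3 <- data.table::data.table(chrom = "c", pos = 1:3, strand = "+",
                                   context = "CG", n_meth = 0L,
                                   n_total = c(3L, 4L, 5L))
  f <- coverage_filter(calls3, 4L)
  expect_identical(nrow(f$calls), 2L)
  expect_equal(f$coverage_fraction, 2 / 3)
})

test_that("Poisson coverage passes the filter at the analytic tail rate", {
  set.seed(5)
  n <- 20000
  calls <- data.table::data.table(chrom = "c", pos = seq_len(n), strand = "+",
                                  context = "CHH", n_meth = 0L,
                                  n_total = rpois(n, 10))
  f <- coverage_filter(calls, 4L)
  expect_equal(f$coverage_fraction, ppois(3, 10, lower.tail = FALSE),
               tolerance = 0.01)
})

test_that("weighted methylation pools counts, not per-site ratios", {
  calls <- data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
                                  strand = "+", context = "CG",
                                  n_meth = c(3L, 1L), n_total = c(10L, 10L))
  expect_equal(weighted_methylation(calls, "chr1", 0, 100, "CG"), 0.2)
  expect_true(is.na(weighted_methylation(calls, "chr1", 0, 100, "CHH")))
  expect_error(weighted_methylation(calls, "chr1", 50, 50), "invalid interval")
})

test_that("weighted methylation equals the brute-force oracle on random regions", {
  calls <- random_calls(300, 2000, seed = 9)
  set.seed(10)
  for (i in 1:25) {
    s <- sample(0:1900, 1); e <- s + sample(10:100, 1)
    ctx <- sample(c("CG", "CHG", "CHH", "all"), 1)
    expect_identical(weighted_methylation(calls, "chr1", s, e, ctx),
                     weighted_oracle(calls, "chr1", s, e, ctx))
  }
})

test_that("window levels are order-invariant and conserve pooled counts", {
  calls <- random_calls(400, 3000, seed = 11)
  w1 <- make_windows(calls, c(chr1 = 3000), 100)
  w2 <- make_windows(calls[sample(.N)], c(chr1 = 3000), 100)
  expect_equal(w1, w2)
  # recombining window count sums reproduces the chromosome-wide level
  for (ctx in c("CG", "CHG", "CHH")) {
    sub <- w1[context == ctx]
    expect_equal(sum(sub$sum_meth) / sum(sub$sum_total),
                 weighted_methylation(calls, "chr1", 0, 3000, ctx))
  }
  # a window containing a whole region reproduces its weighted level
  expect_equal(w1[context == "CG" & start == 0, m],
               weighted_methylation(calls, "chr1", 0, 100, "CG"))
})

test_that("window grids tile and slide with the closed-form window count", {
  calls <- random_calls(10, 240, seed = 3)
  w <- make_windows(calls, c(chr1 = 250), 100)
  grid <- unique(w[, .(start, end)])
  expect_equal(grid$start, c(0L, 100L, 200L))
  expect_equal(grid$end, c(100L, 200L, 250L))
  # sliding 500 kb / 100 kb windows on a 1 Mb chromosome
  win <- dielmeth:::.window_starts(1e6, 5e5, 1e5)
  expect_length(win, ceiling((1e6 - 5e5) / 1e5) + 1)
  for (L in c(120L, 1000L, 1050L, 999L)) {
    s <- dielmeth:::.window_starts(L, 100, 50)
    expect_length(s, if (L <= 100) 1L else ceiling((L - 100) / 50) + 1)
    expect_true(all(s + 100 >= c(s[-1], L)))  # contiguous coverage
  }
})

test_that("replicate correlation handles exact, inverted and noisy replicates", {
  calls <- random_calls(500, 5000, seed = 21)
  w <- make_windows(calls, c(chr1 = 5000), 100)
  expect_equal(replicate_correlation(w, w, "CG"), 1)
  winv <- data.table::copy(w)[, m := 1 - m]
  expect_equal(replicate_correlation(w, winv, "CG"), -1)
})

test_that("synthetic replicates at 30x correlate above 0.95 per context", {
  cfg <- tiny_cfg(seed = 55L, mean_coverage = 30)
  st <- simulate_study(cfg)
  sl <- st$genome$seqlens
  w1 <- make_windows(st$calls[["green_10am_r1"]], sl, 100)
  w2 <- make_windows(st$calls[["green_10am_r2"]], sl, 100)
  for (ctx in c("CG", "CHG", "CHH"))
    expect_gt(replicate_correlation(w1, w2, ctx), 0.95)
})

test_that("pooling replicates sums counts per cytosine", {
  a <- random_calls(100, 500, seed = 31)
  b <- random_calls(100, 500, seed = 31)
  p <- pool_calls(list(a, b))
  expect_equal(sum(p$n_total), sum(a$n_total) + sum(b$n_total))
  expect_identical(nrow(p), nrow(a))
})

test_that("CG strand merging sums symmetric pairs and keeps other contexts", {
  g <- GenomeModel(seqs = Biostrings::DNAStringSet(c(c1 = "AACGTCAGA")))
  # plus CG at pos 3, minus CG at pos 4; plus CHG at pos 6 (CAG)
  calls <- data.table::data.table(
    chrom = "c1", pos = c(3L, 4L, 6L), strand = c("+", "-", "+"),
    context = c("CG", "CG", "CHG"),
    n_meth = c(3L, 2L, 1L), n_total = c(10L, 8L, 5L))
  m <- merge_cg_strands(calls)
  expect_identical(nrow(m), 2L)
  cg <- m[context == "CG"]
  expect_identical(cg$pos, 3L)
  expect_identical(cg$n_meth, 5L)
  expect_identical(cg$n_total, 18L)
  expect_identical(m[context == "CHG", n_total], 5L)
  # weighted level of the merged record equals the pooled level
  expect_equal(cg$n_meth / cg$n_total, 5 / 18)
})
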