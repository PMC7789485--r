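# DMR-gene linking, DEG association, GO enrichment, per-gene dynamics.

mk_dmr <- function(s, e, ctx = "CHH", chrom = "chr1") data.table::data.table(
  chrom = chrom, start = s, end = e, context = ctx, m_a = 0.5, m_b = 0.1,
  delta = 0.4, direction = "hyper", p_value = 1e-9, q_value = 1e-8,
  n_cytosines = 10L, meth_a = 100, total_a = 200, meth_b = 20,
  total_b = 200, comparison_a = "A", comparison_b = "B")

link_genome <- function(strand = "+") {
  GenomeModel(
    Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 40000), collapse = ""))),
    genes = data.table::data.table(gene_id = "g1", chrom = "chr1",
                                   start = 10000L, end = 13000L,
                                   strand = strand),
    exons = data.table::data.table(gene_id = "g1", chrom = "chr1",
                                   start = 10000L, end = 13000L,
                                   strand = strand))
}

test_that("the 2-kb linking envelope is exact at its boundaries", {
  g <- link_genome("+")
  # DMR ending 1999 bp upstream of the TSS: overlaps the envelope
  lk <- link_dmrs_to_genes(mk_dmr(7900L, 8001L), g)
  expect_identical(nrow(lk), 1L)
  expect_identical(lk$zone, "upstream")
  # DMR ending exactly 2001 bp upstream: outside
  expect_identical(nrow(link_dmrs_to_genes(mk_dmr(7900L, 7999L), g)), 0L)
  # straddling body and flank -> body
  expect_identical(link_dmrs_to_genes(mk_dmr(9900L, 10100L), g)$zone, "body")
  # minus-strand gene: a DMR past the genomic end is upstream
  gm <- link_genome("-")
  expect_identical(link_dmrs_to_genes(mk_dmr(13500L, 13600L), gm)$zone,
                   "upstream")
  expect_identical(link_dmrs_to_genes(mk_dmr(8500L, 8600L), gm)$zone,
                   "downstream")
})

test_that("link sets are invariant under a constant coordinate shift", {
  g <- link_genome("+")
  d <- rbind(mk_dmr(8100L, 8300L), mk_dmr(11000L, 11200L),
             mk_dmr(14500L, 14700L))
  lk1 <- link_dmrs_to_genes(d, g)
  off <- 5000L
  g2 <- link_genome("+")
  g2$genes[, `:=`(start = start + off, end = end + off)]
  g2$exons[, `:=`(start = start + off, end = end + off)]
  d2 <- data.table::copy(d)[, `:=`(start = start + off, end = end + off)]
  lk2 <- link_dmrs_to_genes(d2, g2)
  expect_identical(lk1$zone, lk2$zone)
  expect_equal(lk2$start - lk1$start, rep(off, nrow(lk1)))
})

test_that("the headline DMR-associated fraction deduplicates genes", {
  g <- link_genome("+")
  de <- data.table::data.table(gene_id = c("g1", "g2"),
                               status = c("up_in_A", "up_in_B"))
  # two DMRs on the same gene count once in the headline fraction
  links <- link_dmrs_to_genes(rbind(mk_dmr(10100L, 10200L),
                                    mk_dmr(10100L, 10200L),
                                    mk_dmr(12000L, 12100L, ctx = "CG")), g)
  a <- dmr_associated_degs(links, de)
  expect_identical(a$summary$n_dmr_associated, 1L)
  expect_equal(a$summary$fraction, 0.5)
  # but once per stratum in the breakdown
  expect_identical(nrow(a$breakdown), 2L)
  # no DMRs -> fraction 0
  a0 <- dmr_associated_degs(links[0], de)
  expect_equal(a0$summary$fraction, 0)
})

test_that("hypergeometric enrichment matches the closed form and enumeration", {
  # N=20, K=5, n=10, k=5
  pop <- sprintf("p%02d", 1:20)
  gm <- data.table::data.table(gene_id = pop[1:5], go_id = "GO:X")
  study <- pop[1:10]
  res <- go_enrichment(study, pop, gm, p_cut = 1)
  expect_equal(res$p_value, choose(15, 5) / choose(20, 10))
  expect_equal(res$p_value, hyper_upper_oracle(5, 5, 10, 20))
  # k = 0 gives p = 1 and never clears the reporting cutoff
  gm2 <- data.table::data.table(gene_id = pop[11:15], go_id = "GO:Y")
  res2 <- go_enrichment(pop[1:10], pop, gm2, p_cut = 1)
  expect_equal(res2$p_value, 1)
  expect_identical(nrow(go_enrichment(pop[1:10], pop, gm2, p_cut = 0.01)), 0L)
  # random configurations against the choose() oracle
  set.seed(13)
  for (i in 1:50) {
    N <- sample(8:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    p <- pop <- sprintf("q%03d", 1:N)
    gmap <- data.table::data.table(gene_id = pop[seq_len(K)], go_id = "GO:Z")
    study <- sample(pop, n)
    k <- sum(study %in% pop[seq_len(K)])
    res <- go_enrichment(study, pop, gmap, p_cut = 1)
    expect_equal(res$p_value, hyper_upper_oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("a planted GO term is recovered from synthetic DE genes", {
  cfg <- tiny_cfg(seed = 61L)
  truth <- list(genes = data.table::data.table(
    gene_id = sprintf("g%03d", 1:120),
    de = c(rep(TRUE, 35), rep(FALSE, 85))))
  gm <- simulate_go_map(NULL, truth, cfg, n_terms = 30L)
  res <- go_enrichment(truth$genes[de == TRUE, gene_id],
                       truth$genes$gene_id, gm, p_cut = 0.01)
  expect_true("GO:9999999" %in% res$go_id)
  expect_identical(res$go_id[1], "GO:9999999")
})

test_that("methylation-by-expression yields the planted repression ordering", {
  st <- tiny_study()
  ss <- st$samples
  green <- pool_calls(st$calls[ss[tissue == "green" & time == "10am",
                                  sample_id]])
  rl <- region_level_table(green, st$genome$genes, st$genome$seqlens)
  counts <- st$counts[, ss[tissue == "green" & time == "10am", sample_id]]
  f <- fpkm(counts, st$gene_lengths)
  strata <- expression_strata(rowMeans(f), "three_class")
  mb <- methylation_by_expression(rl, strata)
  expect_identical(
    nrow(mb$summary),
    nrow(unique(mb$summary[, .(stratum, region, context)])))
  # silent genes carry the promoter non-CG boost: unexpressed > high
  up <- mb$summary[region == "upstream2k" & context == "CHH"]
  expect_gt(up[stratum == "unexpressed", median_m],
            up[stratum == "high", median_m])
  # identical methylation in both strata gives p = 1
  rl_const <- data.table::copy(rl)[, m := 0.3]
  mb2 <- methylation_by_expression(rl_const, strata)
  expect_true(all(mb2$tests$p_value == 1, na.rm = TRUE))
})

test_that("per-gene bin dynamics are 60 bins, oriented and error-checked", {
  st <- tiny_study()
  gid <- st$genome$genes$gene_id[1]
  gb <- gene_bin_dynamics(st$calls[1:2], st$genome, gid)
  expect_identical(nrow(gb$bins), 2L * 3L * 60L)
  expect_identical(max(gb$bins$bin_index), 60L)
  expect_error(gene_bin_dynamics(st$calls[1:2], st$genome, "nope"),
               "unknown gene id")
  # uniform methylation -> equal bins
  calls <- data.table::data.table(chrom = "chr1", pos = 1:16000, strand = "+",
                                  context = "CG", n_meth = 20L, n_total = 50L)
  g <- link_genome("+")
  gb2 <- gene_bin_dynamics(list(s = calls), g, "g1")
  m <- gb2$bins[context == "CG", m]
  expect_true(all(abs(m - 0.4) < 1e-9))
})
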