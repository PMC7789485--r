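# Shared fixtures and independent oracles for the test suite.

.fixture_env <- new.env(parent = emptyenv())

tiny_cfg <- function(seed = 101L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 1L, chrom_len = 1.5e5, control_len = 6e3,
         n_genes = 10L, n_tes = 15L,
         n_planted_dmrs = c(CG = 3L, CHG = 3L, CHH = 3L),
         n_de_genes = 6L, mean_coverage = 15),
    list(...))
  do.call(sim_config, args)
}

# one small study shared across test files (generation is deterministic)
tiny_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(tiny_cfg())
  .fixture_env$study
}

# --- independent oracles -------------------------------------------------

# two-sided Fisher p by full enumeration over the hypergeometric support,
# using choose() only
fisher_oracle <- function(a, b, c_, d_) {
  K <- a + b; NK <- c_ + d_; m <- a + c_; N <- K + NK
  if (K == 0 || NK == 0 || m == 0 || (b + d_) == 0) return(1)
  x <- max(0, m - NK):min(K, m)
  pr <- choose(K, x) * choose(NK, m - x) / choose(N, m)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# hypergeometric upper tail by choose() enumeration
hyper_upper_oracle <- function(k, K, n, N) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# brute-force weighted methylation by plain-R loop over records
weighted_oracle <- function(calls, chrom, start, end, context) {
  df <- as.data.frame(calls)
  meth <- 0; tot <- 0
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] == chrom && df$pos[i] > start && df$pos[i] <= end &&
        (context == "all" || df$context[i] == context)) {
      meth <- meth + df$n_meth[i]; tot <- tot + df$n_total[i]
    }
  }
  if (tot == 0) NA_real_ else meth / tot
}

# small random call set on one chromosome
random_calls <- function(n = 200, L = 1000, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(L, n))
  tot <- rpois(n, 8)
  data.table::data.table(
    chrom = "chr1", pos = pos,
    strand = sample(c("+", "-"), n, TRUE),
    context = sample(c("CG", "CHG", "CHH"), n, TRUE),
    n_meth = rbinom(n, tot, 0.3), n_total = tot)
}
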