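# Expression quantification, stratification and a minimal NB test.
#
# FPKM = count * 1e9 / (exonic length * library size). Genes with
# FPKM > 0.5 are "expressed" (the study's rule). The differential test is a
# deliberately minimal negative-binomial Wald test (median-of-ratios size
# factors, one pooled method-of-moments dispersion with a floor); it is not
# DESeq2 and output metadata says so.

#' FPKM from raw counts
#'
#' @param counts gene x sample matrix (or data.frame) of raw counts, gene
#'   ids as rownames.
#' @param gene_lengths named vector of exonic lengths (bp).
#' @param library_sizes named vector of per-sample totals; defaults to
#'   column sums of `counts`.
#' @return matrix of FPKM values, same dimnames as `counts`.
#' @export
#' @examples
#' fpkm(matrix(100, 1, 1, dimnames = list("g1", "s1")),
#'      c(g1 = 1000), c(s1 = 1e6))   # 100
fpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  .assert(all(rownames(counts) %in% names(gene_lengths)),
          "gene_lengths must cover all genes")
  len <- gene_lengths[rownames(counts)]
  .assert(all(len > 0), "gene lengths must be positive")
  ls <- library_sizes[colnames(counts)]
  .assert(all(ls > 0), "library sizes must be positive")
  sweep(counts / len, 2, ls, "/") * 1e9
}

#' Expression strata from FPKM values
#'
#' Quintile mode ranks expressed genes (FPKM > `expressed_cutoff`) by the
#' chosen FPKM vector and splits them into five near-equal groups (group 1 =
#' lowest expression), ties broken by stable gene-id order. Three-class mode
#' labels unexpressed genes (FPKM <= cutoff) and splits the expressed genes
#' at terciles into lowly / highly expressed, dropping the middle tercile.
#'
#' @param fpkm_values named numeric vector (one ranking sample or a group
#'   mean).
#' @param mode `"quintiles"` or `"three_class"`.
#' @param expressed_cutoff FPKM cutoff for "expressed" (default 0.5).
#' @return data.table `gene_id, fpkm, stratum`; quintile strata are
#'   `"Q1"`..`"Q5"` (unexpressed genes NA), three-class strata are
#'   `"unexpressed"`, `"low"`, `"high"` (middle tercile NA).
#' @export
expression_strata <- function(fpkm_values,
                              mode = c("quintiles", "three_class"),
                              expressed_cutoff = 0.5) {
  mode <- match.arg(mode)
  .assert(!is.null(names(fpkm_values)), "fpkm_values must be named by gene")
  out <- data.table::data.table(gene_id = names(fpkm_values),
                                fpkm = as.numeric(fpkm_values))
  expressed <- out$fpkm > expressed_cutoff
  out[, stratum := NA_character_]
  if (mode == "quintiles") {
    n_ex <- sum(expressed)
    .assert(n_ex >= 5L, "need at least 5 expressed genes for quintiles")
    idx <- which(expressed)
    ord <- idx[order(out$fpkm[idx], out$gene_id[idx])]
    q <- ceiling(seq_along(ord) * 5 / n_ex)
    out[ord, stratum := paste0("Q", q)]
  } else {
    out[!expressed, stratum := "unexpressed"]
    idx <- which(expressed)
    if (length(idx)) {
      ord <- idx[order(out$fpkm[idx], out$gene_id[idx])]
      t3 <- ceiling(seq_along(ord) * 3 / length(ord))
      out[ord[t3 == 1L], stratum := "low"]
      out[ord[t3 == 3L], stratum := "high"]
    }
  }
  out[]
}

# median-of-ratios size factors (DESeq-style)
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  .assert(any(use), "no gene with all-positive counts for size factors")
  apply(counts, 2, function(k) exp(median(log(k[use]) - lg[use])))
}

# pooled method-of-moments NB dispersion with a small-sample floor
pooled_dispersion <- function(norm_a, norm_b, floor = 0.01, min_mean = 10) {
  mu <- cbind(rowMeans(norm_a), rowMeans(norm_b))
  v <- cbind(apply(norm_a, 1, var), apply(norm_b, 1, var))
  mbar <- rowMeans(mu)
  keep <- is.finite(mbar) & mbar >= min_mean
  num <- sum(rowMeans(v)[keep] - mbar[keep])
  den <- sum(mbar[keep]^2)
  max(floor, num / den)
}

#' Minimal negative-binomial differential-expression test
#'
#' Two-condition Wald test on the log2 fold change of size-factor-normalised
#' means, with a single pooled method-of-moments dispersion (floored).
#' Benjamini-Hochberg q-values; status at `q <= alpha` with no fold-change
#' floor. All-zero genes are flagged `ns`.
#'
#' @param counts_a,counts_b gene x replicate count matrices (>= 2 replicates
#'   each), same genes in the same order.
#' @param alpha significance level on q.
#' @return data.table `gene_id, base_mean_a, base_mean_b, log2fc, p_value,
#'   q_value, status` with status in `c("up_in_A", "up_in_B", "ns")`.
#'   Attributes: `dispersion`, `size_factors`, `method` (names the test so
#'   results are not conflated with DESeq2).
#' @export
de_test <- function(counts_a, counts_b, alpha = 0.05) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  .assert(ncol(counts_a) >= 2L && ncol(counts_b) >= 2L,
          "need >= 2 replicates per group")
  .assert(nrow(counts_a) == nrow(counts_b), "gene sets differ")
  genes <- rownames(counts_a) %||% sprintf("gene%06d", seq_len(nrow(counts_a)))
  sf <- size_factors(cbind(counts_a, counts_b))
  na <- ncol(counts_a); nb <- ncol(counts_b)
  qa <- sweep(counts_a, 2, sf[seq_len(na)], "/")
  qb <- sweep(counts_b, 2, sf[na + seq_len(nb)], "/")
  disp <- pooled_dispersion(qa, qb)
  mu_a <- rowMeans(qa); mu_b <- rowMeans(qb)
  pseudo <- 0.5
  l2fc <- log2((mu_a + pseudo) / (mu_b + pseudo))
  se2 <- ((1 / (mu_a + pseudo) + disp) / na +
            (1 / (mu_b + pseudo) + disp) / nb) / log(2)^2
  z <- l2fc / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  allzero <- mu_a + mu_b == 0
  p[allzero] <- NA_real_
  q <- bh_adjust(p)
  status <- ifelse(!is.na(q) & q <= alpha,
                   ifelse(l2fc > 0, "up_in_A", "up_in_B"), "ns")
  out <- data.table::data.table(gene_id = genes, base_mean_a = mu_a,
                                base_mean_b = mu_b, log2fc = l2fc,
                                p_value = p, q_value = q, status = status)
  data.table::setattr(out, "dispersion", disp)
  data.table::setattr(out, "size_factors", sf)
  data.table::setattr(out, "method",
                      "minimal NB Wald (median-of-ratios, pooled MoM dispersion); not DESeq2")
  out[]
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration over all group assignments of the pooled mid-ranks for
#' small samples (handles ties exactly: identical samples give p = 1);
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x shifted left of y) or
#'   `"greater"`.
#' @param exact_max use exact enumeration when `length(x) + length(y)` is at
#'   most this (default 20).
#' @return the p-value.
#' @export
#' @examples
#' mannwhitney(1:3, 4:6, "less")   # 1 / choose(6, 3) = 0.05
mannwhitney <- function(x, y,
                        alternative = c("two.sided", "less", "greater"),
                        exact_max = 20L) {
  alternative <- match.arg(alternative)
  .assert(length(x) >= 1L && length(y) >= 1L, "need >= 1 value per group")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])          # rank sum of x
  if (n <= exact_max) {
    combs <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    tol <- 1e-9
    mu <- n1 * (n + 1) / 2
    switch(alternative,
      less = mean(w_all <= w_obs + tol),
      greater = mean(w_all >= w_obs - tol),
      two.sided = mean(abs(w_all - mu) >= abs(w_obs - mu) - tol))
  } else {
    u_obs <- w_obs - n1 * (n1 + 1) / 2
    mu_u <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    sig <- sqrt(sigma2)
    cc <- 0.5
    switch(alternative,
      less = pnorm((u_obs - mu_u + cc) / sig),
      greater = pnorm((u_obs - mu_u - cc) / sig, lower.tail = FALSE),
      two.sided = {
        z <- u_obs - mu_u
        z <- sign(z) * max(0, abs(z) - cc)
        min(1, 2 * pnorm(-abs(z) / sig))
      })
  }
}
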