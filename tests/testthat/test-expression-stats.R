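# Differential abundance, allele intersection, translational efficiency,
# and the distribution-level tests.

test_that("size factors are median ratios with the expected invariances", {
  set.seed(1)
  base <- rpois(300, 100) + 1
  m <- cbind(s1 = base, s2 = 2L * base, s3 = base)
  sf <- size_factors(m)
  expect_equal(sf[["s2"]] / sf[["s1"]], 2, tolerance = 1e-9)
  expect_equal(sf[["s1"]], sf[["s3"]])
  # the ratio to the per-feature geometric mean makes a global rescaling a
  # no-op, while rescaling one library rescales that library's factor
  expect_equal(size_factors(3 * m), sf, tolerance = 1e-9)
  m2 <- m; m2[, 1] <- 5L * m2[, 1]
  sf2 <- size_factors(m2)
  expect_equal(sf2[["s1"]] / sf2[["s3"]], 5 * sf[["s1"]] / sf[["s3"]],
               tolerance = 1e-9)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "pseudocount")
})

test_that("TPM floors map to molecules per cell (3 TPM ~ 10 molecules)", {
  expect_equal(3 / 1e6 * 3.4e6, 10.2)
  set.seed(2)
  counts <- matrix(rpois(400, 200), ncol = 4,
                   dimnames = list(sprintf("f%03d", 1:100), NULL))
  tp <- tpm(counts, lengths = rep(1000, 100))
  expect_equal(unname(colSums(tp)), rep(1e6, 4))
})

test_that("the NB test is calibrated on null data", {
  set.seed(10)
  n <- 2000
  counts <- matrix(rnbinom(n * 8, mu = rep(exp(runif(n, 3, 7)), 8),
                           size = 1 / 0.05), nrow = n,
                   dimnames = list(sprintf("g%04d", 1:n), NULL))
  grp <- rep(c("control", "mutant"), each = 4)
  de <- nb_differential(counts, grp, lengths = rep(1500, n))
  called <- sum(de$fdr < 0.01, na.rm = TRUE)
  expect_lte(called / n, 0.02)
})

test_that("a planted 2-fold change is recovered in both alleles", {
  set.seed(11)
  n <- 500
  mu <- exp(runif(n, 6, 8))
  fold <- rep(1, n); fold[1:10] <- 2
  mk <- function(n_ctrl, n_mut) {
    m <- cbind(
      matrix(rnbinom(n * n_ctrl, mu = rep(mu, n_ctrl), size = 1 / 0.05),
             nrow = n),
      matrix(rnbinom(n * n_mut, mu = rep(mu * fold, n_mut), size = 1 / 0.05),
             nrow = n))
    rownames(m) <- sprintf("g%04d", 1:n)
    list(counts = m, grp = rep(c("control", "mutant"), c(n_ctrl, n_mut)))
  }
  em1 <- mk(8, 7); em2 <- mk(8, 7)
  de1 <- nb_differential(em1$counts, em1$grp, lengths = rep(1500, n))
  de2 <- nb_differential(em2$counts, em2$grp, lengths = rep(1500, n))
  expect_gte(sum(de1$fdr[1:10] < 0.01), 9)
  expect_gte(sum(de2$fdr[1:10] < 0.01), 9)
  cons <- intersect_alleles(de1, de2)
  expect_gte(sum(cons$called[1:10]), 9)
  expect_lte(sum(cons$called[-(1:10)]), 3)
})

test_that("allele intersection keeps the minimum-magnitude fold change", {
  de1 <- data.frame(feature = c("a", "b", "c"),
                    log2fc = c(1.0, 1.0, 1.0), fdr = c(1e-4, 1e-4, 1e-4))
  de2 <- data.frame(feature = c("a", "b", "c"),
                    log2fc = c(1.5, -1.0, 1.2), fdr = c(1e-3, 1e-3, 0.02))
  res <- intersect_alleles(de1, de2)
  expect_true(res$called[1]);  expect_equal(res$log2fc[1], 1.0)
  expect_false(res$called[2])                      # opposite signs
  expect_false(res$called[3])                      # em2 FDR 0.02 >= 0.01
})

test_that("translational efficiency is a ratio of ratios with the RFP floor", {
  set.seed(12)
  n <- 300
  mu <- exp(runif(n, 4, 7))
  grp <- rep(c("control", "mutant"), each = 4)
  rna <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 50), nrow = n,
                dimnames = list(sprintf("g%03d", 1:n), NULL))
  rfp <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 50), nrow = n,
                dimnames = list(sprintf("g%03d", 1:n), NULL))
  rfp[1, ] <- rpois(8, 2)     # a feature with negligible ribosome occupancy
  te <- translational_efficiency(rfp, rna, grp, lengths = rep(1000, n))
  # doubling both assays leaves TE unchanged
  te2 <- translational_efficiency(2L * rfp, 2L * rna, grp,
                                  lengths = rep(1000, n))
  expect_equal(te$te_control, te2$te_control, tolerance = 1e-9)
  # features below 10 TPM ribosome occupancy in control are excluded
  expect_true(te$excluded[1])
  # null data: differential TE call rate at most 2x nominal
  expect_lte(sum(te$fdr < 0.01, na.rm = TRUE) / sum(!te$excluded), 0.02)
})

test_that("KS comparison matches the brute-force ECDF gap", {
  expect_equal(ks_compare(1:10, 1:10), list(D = 0, p = 1))
  d <- ks_compare(1:10, 101:110)
  expect_equal(d$D, 1)
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1)); y <- rnorm(sample(5:50, 1), mean = 0.5)
    expect_equal(ks_compare(x, y)$D, oracle_ks_D(x, y), tolerance = 1e-12)
  }
  expect_error(ks_compare(1, 1:5), ">= 2")
})

test_that("Mann-Whitney exact p agrees with full enumeration at n = 4 + 4", {
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4, mean = runif(1, 0, 2))
    mw <- mw_compare(x, y)
    expect_equal(mw$p, oracle_mw_p(x, y), tolerance = 1e-12)
    # U + U' = nA * nB
    expect_equal(mw$U + mw_compare(y, x)$U, 16)
  }
  # identical groups (ties force the corrected normal approximation)
  expect_gte(mw_compare(1:6, 1:6)$p, 0.9)
})

test_that("BH adjustment reproduces the step-up procedure and is monotone", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.36)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  set.seed(15)
  pr <- runif(50)
  adj <- bh_adjust(pr)
  expect_equal(adj, oracle_bh(pr), tolerance = 1e-12)
  r1 <- sum(adj < 0.05); r2 <- sum(adj < 0.1)
  expect_lte(r1, r2)
})

test_that("Kruskal-Wallis wrapper returns BH-corrected pairwise tests", {
  set.seed(16)
  v <- c(rnorm(10), rnorm(10, 2), rnorm(10, 2))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- kw_with_pairwise(v, g)
  expect_lt(res$kw$p.value, 0.01)
  expect_equal(nrow(res$pairwise), 3)
  expect_equal(res$pairwise$fdr, bh_adjust(res$pairwise$p))
})

test_that("DE calls vanish on permuted labels of a synthetic dataset", {
  cfg <- small_cfg(51)
  pool <- gen_pirna_pool(cfg)
  sim <- gen_transcriptome_with_sites(cfg, pool)
  cm <- gen_count_matrices(sim$truth, sim, cfg)
  grp <- ifelse(cm$rna$samples$genotype == "control", "control", "mutant")
  set.seed(52)
  perm <- sample(grp)
  while (all(perm == grp)) perm <- sample(grp)
  de <- nb_differential(cm$rna$counts, perm, lengths = cm$lengths)
  expect_lte(sum(de$fdr < 0.01, na.rm = TRUE), 2)
})

test_that("the NB test broadly agrees with an established NB framework", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  n <- 400
  mu <- exp(runif(n, 4, 7))
  fold <- rep(1, n); fold[1:12] <- 2.5
  counts <- cbind(
    matrix(rnbinom(n * 4, mu = rep(mu, 4), size = 1 / 0.02), nrow = n),
    matrix(rnbinom(n * 4, mu = rep(mu * fold, 4), size = 1 / 0.02),
           nrow = n))
  rownames(counts) <- sprintf("g%03d", 1:n)
  colnames(counts) <- sprintf("s%d", 1:8)
  grp <- rep(c("control", "mutant"), each = 4)
  de <- nb_differential(counts, grp, lengths = rep(1000, n))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, S4Vectors::DataFrame(condition = factor(grp)), ~condition)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  ours <- de$feature[which(de$fdr < 0.01)]
  theirs <- rownames(res)[which(res$padj < 0.01)]
  # both recover the planted set; call overlap, not numerical identity
  planted <- sprintf("g%03d", 1:12)
  expect_gte(length(intersect(ours, planted)), 10)
  expect_gte(length(intersect(theirs, planted)), 10)
  expect_gte(length(intersect(ours, theirs)) /
               max(length(union(ours, theirs)), 1), 0.6)
})
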