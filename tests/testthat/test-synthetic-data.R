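# Synthetic-data generator: determinism, normalisation, planted ground truth.

test_that("pool generation is a pure function of (config, seed)", {
  cfg <- sim_config(seed = 1, n_pirnas = 100L)
  p1 <- gen_pirna_pool(cfg)
  p2 <- gen_pirna_pool(cfg)
  expect_identical(p1, p2)
  p3 <- gen_pirna_pool(sim_config(seed = 2, n_pirnas = 100L))
  expect_false(identical(p1$info$sequence, p3$info$sequence))
})

test_that("each simulated replicate sums to 1e6 ppm and prefixes are unique", {
  cfg <- small_cfg()
  pool <- gen_pirna_pool(cfg)
  expect_equal(unname(colSums(pool$ppm$control)),
               rep(1e6, cfg$n_smallrna_control), tolerance = 1e-6)
  for (j in seq_len(cfg$n_smallrna_mutant)) {
    # mutant residuals are re-added after normalisation: within rounding
    expect_equal(sum(pool$ppm$mutant[, j]), 1e6, tolerance = 1e-5)
  }
  expect_false(anyDuplicated(pool$info$prefix) > 0)
  expect_true(all(nchar(pool$info$prefix) == 25L))
})

test_that("a 4-decade abundance law spans >= 3 decades of concentration", {
  cfg <- sim_config(seed = 5, n_pirnas = 200L, abundance_sdlog = 2.3)
  pool <- gen_pirna_pool(cfg)
  expect_gte(max(pool$mean_ppm) / min(pool$mean_ppm), 1e3)
})

test_that("re-scanning every planted site reproduces the truth tier", {
  for (seed in c(3, 17)) {
    cfg <- small_cfg(seed)
    pool <- gen_pirna_pool(cfg)
    sim <- gen_transcriptome_with_sites(cfg, pool)
    sites <- sim$truth$sites[!sim$truth$sites$decoy &
                               sim$truth$sites$role != "seed_only", ]
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      g <- pool$info$sequence[pool$info$pirna_id == s$pirna_id]
      L <- nchar(g)
      win <- substr(sim$transcripts[[s$transcript_id]], s$t1 - L + 1, s$t1)
      m <- pair_mask(g, win)
      expect_identical(evaluate_tier(m, pool$mean_ppm[[s$pirna_id]]),
                       s$tier)
    }
  }
})

test_that("decoy sites fail every clause and seed-only sites do not qualify", {
  cfg <- small_cfg(7)
  pool <- gen_pirna_pool(cfg)
  sim <- gen_transcriptome_with_sites(cfg, pool)
  others <- sim$truth$sites[sim$truth$sites$decoy |
                              sim$truth$sites$role == "seed_only", ]
  expect_gt(nrow(others), 0)
  for (i in seq_len(nrow(others))) {
    s <- others[i, ]
    g <- pool$info$sequence[pool$info$pirna_id == s$pirna_id]
    L <- nchar(g)
    win <- substr(sim$transcripts[[s$transcript_id]], s$t1 - L + 1, s$t1)
    expect_identical(evaluate_tier(pair_mask(g, win),
                                   pool$mean_ppm[[s$pirna_id]]), "none")
  }
})

test_that("a configuration with zero planted sites yields an empty truth", {
  cfg <- sim_config(seed = 2, n_pirnas = 30L, n_transcripts = 10L,
                    n_targets = 0L, n_bystander_ablated = 0L,
                    n_ctrl_cleaved = 0L, n_bystander_control = 0L,
                    n_seed_only = 0L, n_decoys = 0L)
  sim <- gen_transcriptome_with_sites(cfg, gen_pirna_pool(cfg))
  expect_equal(nrow(sim$truth$sites), 0)
})

test_that("read simulation injects the configured duplicate fraction", {
  cfg <- small_cfg(9, dup_frac = 0.2)
  pool <- gen_pirna_pool(cfg)
  reads <- gen_smallrna_reads(pool, NULL, 1e5, cfg, "control", 1)
  expect_length(reads, 1e5)
  # independent dedup: distinct full reads (UMI5 + insert + adapter + UMI3)
  expect_equal(length(unique(reads)), 0.8 * 1e5, tolerance = 0.01)
  expect_true(all(grepl("TGGAATTCTCGGGTGCCAAGG", reads, fixed = TRUE)))
})

test_that("species read counts follow their ppm (binomial sampling)", {
  cfg <- small_cfg(13, dup_frac = 0)
  pool <- gen_pirna_pool(cfg)
  depth <- 2e5
  reads <- gen_smallrna_reads(pool, NULL, depth, cfg, "control", 1)
  # count reads whose insert starts with each species prefix
  ins <- substr(reads, 10L, 10L + 24L)
  cnt <- table(factor(ins, levels = pool$info$prefix))
  expected <- pool$ppm$control[, 1] / 1e6 * depth
  big <- expected > 500
  expect_true(all(abs(cnt[big] - expected[big]) <
                    5 * sqrt(expected[big]) + 5))
})

test_that("degradome signal collapses with the guide locus and background stays low", {
  cfg <- small_cfg(21)
  pool <- gen_pirna_pool(cfg)
  sim <- gen_transcriptome_with_sites(cfg, pool)
  deg <- gen_degradome(sim$truth, pool, sim, cfg)
  truth <- sim$truth$sites
  targets <- truth[truth$role == "target", ]
  sig <- collapse_five_prime(deg, lib_sizes = setNames(
    rep(attr(deg, "depth"), length(unique(deg$replicate))),
    unique(deg$replicate)))
  site_mean <- function(s, gt) {
    sel <- sig$transcript_id == s$transcript_id &
      sig$pos == s$predicted_cleavage & sig$genotype == gt
    n_reps <- if (gt == "control") cfg$n_degradome_control else
      cfg$n_degradome_mutant
    sum(sig$ppm[sel]) / n_reps
  }
  ctrl <- vapply(seq_len(nrow(targets)),
                 function(i) site_mean(targets[i, ], "control"), numeric(1))
  mut <- vapply(seq_len(nrow(targets)),
                function(i) site_mean(targets[i, ], "mutant"), numeric(1))
  # ablation factor 100 in expectation; demand at least the 8-fold structure
  expect_true(mean(mut / pmax(ctrl, 1e-9) <= 1 / 8) >= 0.9)
  # background-only transcripts: no position above the 0.1 ppm threshold
  planted_tx <- unique(truth$transcript_id)
  bg <- sig[!(sig$transcript_id %in% planted_tx), ]
  expect_gt(nrow(bg), 0)
  expect_true(all(bg$ppm <= 0.1))
})

test_that("count matrices are deterministic and apply the derepression fold", {
  cfg <- small_cfg(31)
  pool <- gen_pirna_pool(cfg)
  sim <- gen_transcriptome_with_sites(cfg, pool)
  c1 <- gen_count_matrices(sim$truth, sim, cfg)
  c2 <- gen_count_matrices(sim$truth, sim, cfg)
  expect_identical(c1, c2)
  expect_true(all(c1$fold >= 1))
  dr <- names(c1$fold)[c1$fold > 1.5]
  expect_gt(length(dr), 0)
  mut <- c1$rna$samples$genotype == "mutant"
  obs <- rowMeans(c1$rna$counts[dr, mut, drop = FALSE]) /
    rowMeans(c1$rna$counts[dr, !mut, drop = FALSE])
  expect_gt(median(obs), 1.3)
})
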