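# Small RNA quantification: trimming, UMI dedup, prefix grouping, filters,
# absolute quantification.

adapter <- "TGGAATTCTCGGGTGCCAAGG"
mk_read <- function(insert, u5 = "AAACCCGGG", u3 = "TTTAAACCC") {
  paste0(u5, insert, adapter, u3)
}

test_that("adapter trimming recovers inserts and tolerates one mismatch", {
  ins <- paste(rep("ACGT", 7), collapse = "")    # 28 nt
  td <- trim_and_dedup(mk_read(ins))
  expect_identical(td$inserts, ins)
  expect_identical(td$umi5, "AAACCCGGG")
  expect_identical(td$umi3, "TTTAAACCC")
  # one mismatch in the 8-nt anchor
  bad_ad <- paste0("TGGAATCC", substr(adapter, 9, nchar(adapter)))
  td2 <- trim_and_dedup(paste0("AAACCCGGG", ins, bad_ad, "TTTAAACCC"))
  expect_identical(td2$inserts, ins)
  # no adapter: read dropped and tallied
  td3 <- trim_and_dedup(paste0("AAACCCGGG", ins, "TTTAAACCC"))
  expect_length(td3$inserts, 0)
  expect_equal(td3$log$no_adapter, 1)
})

test_that("PCR duplicates collapse on the (UMI5, insert, UMI3) triple", {
  ins <- paste(rep("AC", 14), collapse = "")
  reads <- c(mk_read(ins), mk_read(ins),                     # exact dup
             mk_read(ins, u5 = "GGGGGGGGG"))                 # distinct UMI
  td <- trim_and_dedup(reads)
  expect_length(td$inserts, 2)
  expect_equal(td$log$duplicates, 1)
  # idempotence: rebuilding reads from kept records and re-running is stable
  rebuilt <- paste0(td$umi5, td$inserts, adapter, td$umi3)
  expect_length(trim_and_dedup(rebuilt)$inserts, 2)
})

test_that("inserts outside 14-54 nt are discarded", {
  short13 <- paste(rep("A", 13), collapse = "")
  ok14 <- paste(rep("A", 14), collapse = "")
  td <- trim_and_dedup(c(mk_read(short13), mk_read(ok14)))
  expect_identical(td$inserts, ok14)
  expect_equal(td$log$out_of_range, 1)
})

test_that("prefix grouping collapses 3' heterogeneity and conserves ppm", {
  x <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
             collapse = "")
  inserts <- c(paste0(x, "AA"), paste0(x, "G"), paste0(x))
  g <- group_by_prefix(inserts)
  expect_equal(nrow(g), 1)
  expect_equal(g$count, 3)
  expect_equal(sum(g$ppm), 1e6)
  # single insert in a library of 1e6 is 1 ppm by definition
  g2 <- group_by_prefix(paste0(x, "T"), total = 1e6)
  expect_equal(g2$ppm, 1)
  # shorter-than-25 inserts are excluded from grouping but tallied
  g3 <- group_by_prefix(c(inserts, "ACGTACGTACGTAC"))
  expect_equal(attr(g3, "n_short"), 1)
})

test_that("expression filter applies the 1 ppm floor inclusively across replicates", {
  ppm <- rbind(a = c(1.0, 1.0, 1.0), b = c(5, 0.9, 2), c = c(0, 0, 0))
  kept <- filter_expressed(ppm, 1:3)
  expect_identical(rownames(kept), "a")     # exactly 1.0 everywhere is kept
  expect_equal(nrow(filter_expressed(ppm[0, , drop = FALSE], 1:3)), 0)
})

test_that("ablation labels use the 0.1 ppm mean threshold inclusively", {
  ppm <- rbind(a = c(10, 0.05, 0.05), b = c(10, 0.11, 0.11),
               c = c(10, 0.1, 0.1))
  lab <- classify_ablated(ppm, 2:3)
  expect_true(lab[["a"]])
  expect_false(lab[["b"]])
  expect_true(lab[["c"]])                   # boundary: <= 0.1 is ablated
})

test_that("locus deletion ablates its piRNAs in the simulated pool", {
  cfg <- small_cfg(19)
  pool <- gen_pirna_pool(cfg)
  ppm <- cbind(pool$ppm$control, pool$ppm$mutant)
  colnames(ppm) <- c(paste0("c", seq_len(cfg$n_smallrna_control)),
                     paste0("m", seq_len(cfg$n_smallrna_mutant)))
  kept <- filter_expressed(ppm, seq_len(cfg$n_smallrna_control))
  lab <- classify_ablated(kept, cfg$n_smallrna_control +
                            seq_len(cfg$n_smallrna_mutant))
  truth_abl <- pool$info$locus[match(rownames(kept), pool$info$pirna_id)] %in%
    cfg$ablated_loci
  expect_gte(mean(lab == truth_abl), 0.99)
})

test_that("absolute quantification reproduces the molar conversions", {
  # 1 molecule in 1,800 um^3 is ~0.92 pM, reported as about 1 pM
  expect_equal(molecules_to_pM(1, 1800),
               1 / (1.8e-12 * 6.02214076e23) * 1e12, tolerance = 1e-12)
  expect_equal(molecules_to_pM(1, 1800), 0.9225, tolerance = 1e-3)
  # 1 ppm of 1e7 piRNAs per cell is 10 molecules
  expect_equal(ppm_to_molecules(1, 1e7), 10)
  q <- absolute_quantify(ppm = 1, total_per_cell = 1e7, cell_volume = 1800)
  expect_equal(q$molecules, 10)
  expect_equal(q$pM, 9.225, tolerance = 1e-2)
})

test_that("spike-in calibration is linear through the origin", {
  cal <- spike_calibration(counts = c(200, 400, 100), molecules = c(1e5, 2e5, 5e4))
  expect_equal(cal$slope, 0.002, tolerance = 1e-10)
  q1 <- absolute_quantify(counts = 100, calibration = cal, cells = 10)
  # doubling molecules at fixed counts halves the slope and so the estimate
  cal2 <- spike_calibration(c(200, 400, 100), 2 * c(1e5, 2e5, 5e4))
  q2 <- absolute_quantify(counts = 100, calibration = cal2, cells = 10)
  expect_equal(q2$molecules, 2 * q1$molecules)
  expect_error(spike_calibration(c(5, 0), c(1e5, 1e5)), "2 detected")
})

test_that("Poisson detectability matches the closed form and is monotone", {
  expect_equal(poisson_detectability(10), 1 - exp(-10))
  expect_equal(poisson_detectability(10), 0.9999546, tolerance = 1e-7)
  expect_gte(poisson_detectability(10), 0.9999)
  expect_equal(poisson_detectability(0), 0)
  m <- poisson_detectability(seq(0, 20, by = 0.5))
  expect_true(all(diff(m) > 0))
  # NB branch is below Poisson at equal mean (overdispersion spreads zeros)
  expect_lt(poisson_detectability(10, dispersion = 0.5),
            poisson_detectability(10))
  expect_error(poisson_detectability(-1), ">= 0")
})

test_that("simulated reads round-trip to the simulated ppm (r >= 0.99)", {
  cfg <- sim_config(seed = 23)
  pool <- gen_pirna_pool(cfg)
  spikes <- gen_spike_mix(cfg)
  reads <- gen_smallrna_reads(pool, spikes, 1e6, cfg, "control", 1)
  q <- quantify_replicates(list(rep1 = reads), spike_seqs = spikes$sequence)
  idx <- match(pool$info$prefix, rownames(q$ppm))
  expect_true(all(!is.na(idx)))
  expect_gte(cor(pool$ppm$control[, 1], q$ppm[idx, 1]), 0.99)
  # grouping partitions kept inserts: ppm conserves to 1e6
  expect_equal(unname(colSums(q$ppm)), 1e6, tolerance = 1e-6)
  # spike counts scale with the capture rate
  expect_equal(mean(q$spike_counts[, 1]),
               cfg$spike_molecules * cfg$spike_capture, tolerance = 0.2)
})
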