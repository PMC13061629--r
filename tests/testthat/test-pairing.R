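# Pairing engine: masks, tier rules, transcript scans, seed and
# translation-candidate searches.

test_that("pair_mask matches the antiparallel Watson-Crick definition", {
  set.seed(101)
  for (i in 1:25) {
    g <- paste(sample(c("A", "C", "G", "T"), sample(25:30, 1),
                      replace = TRUE), collapse = "")
    w <- paste(sample(c("A", "C", "G", "T"), nchar(g), replace = TRUE),
               collapse = "")
    expect_identical(pair_mask(g, w), oracle_pair_mask(g, w))
  }
  g <- paste(rep("ACGTC", 5), collapse = "")
  expect_true(all(pair_mask(g, revcomp(g))))
  # guide against its own sequence: only palindromic accidents
  expect_identical(pair_mask(g, g), oracle_pair_mask(g, g))
})

test_that("a single mismatch at g10 flips exactly index 10", {
  g <- paste(rep("A", 26), collapse = "")
  w <- revcomp(g)                       # all T
  wc <- strsplit(w, "")[[1]]
  wc[26 - 10 + 1] <- "G"                # base facing g10
  m <- pair_mask(g, paste(wc, collapse = ""))
  expect_false(m[10])
  expect_true(all(m[-10]))
})

test_that("G:U wobble counts as unpaired by default, paired when enabled", {
  g <- paste0("G", paste(rep("A", 25), collapse = ""))
  w <- revcomp(g)
  wc <- strsplit(w, "")[[1]]
  wc[26] <- "T"                         # target U facing guide G1
  w2 <- paste(wc, collapse = "")
  expect_false(pair_mask(g, w2)[1])
  expect_true(pair_mask(g, w2, wobble = TRUE)[1])
})

test_that("tier rules follow the printed abundance-tiered clauses", {
  m20 <- rep(FALSE, 30)
  m20[c(2:10, 12:15, 17:23)] <- TRUE    # 20 paired in g2-g25, no contig run
  expect_identical(evaluate_tier(m20, 2), "extensive20")
  m417 <- rep(FALSE, 30); m417[4:17] <- TRUE
  m417[c(20, 22, 24, 26)] <- TRUE       # 18 paired overall
  expect_identical(evaluate_tier(m417, 60), "contig_g4g17")
  expect_identical(evaluate_tier(rep(TRUE, 30), 0.5), "none")
  # 19 paired in g2-g25 never qualifies the count clause
  m19 <- rep(FALSE, 30)
  m19[c(2:10, 12:15, 17:22)] <- TRUE
  expect_identical(evaluate_tier(m19, 2), "none")
  # the lowest-floor satisfied clause is reported
  m316 <- rep(FALSE, 30); m316[3:16] <- TRUE
  expect_identical(evaluate_tier(m316, 60), "contig_g3g15")
  expect_identical(evaluate_tier(m316, 7), "contig_g3g15")
  expect_identical(evaluate_tier(m316, 3), "none")
})

test_that("tier assignment is monotone in pairing and abundance", {
  set.seed(77)
  rank_of <- function(t) match(t, c("none", "contig_g4g17", "contig_g3g16",
                                    "contig_g3g15", "extensive20"))
  for (i in 1:200) {
    m <- runif(30) < runif(1, 0.3, 0.9)
    ab <- sample(c(0.5, 1, 5, 10, 50, 200), 1)
    t0 <- evaluate_tier(m, ab)
    # adding one paired position never removes qualification
    off <- which(!m)
    if (length(off)) {
      m2 <- m; m2[sample(off, 1)] <- TRUE
      t1 <- evaluate_tier(m2, ab)
      if (t0 != "none") expect_true(t1 != "none")
    }
    # raising abundance never removes qualification
    t2 <- evaluate_tier(m, ab * 10)
    if (t0 != "none") {
      expect_true(t2 != "none")
      expect_gte(rank_of(t2), rank_of(t0))
    }
  }
})

test_that("scan_transcript agrees with the exhaustive window oracle", {
  set.seed(42)
  for (i in 1:30) {
    g <- paste(sample(c("A", "C", "G", "T"), sample(25:30, 1),
                      replace = TRUE), collapse = "")
    tx <- paste(sample(c("A", "C", "G", "T"), sample(80:500, 1),
                       replace = TRUE), collapse = "")
    # plant a qualifying window in a third of the cases
    if (i %% 3 == 0) {
      ins <- revcomp(g)
      pos <- sample(seq_len(nchar(tx) - nchar(ins)), 1)
      tx <- paste0(substr(tx, 1, pos - 1), ins,
                   substr(tx, pos + nchar(ins), nchar(tx)))
    }
    ab <- sample(c(0.5, 2, 7, 60), 1)
    got <- scan_transcript(g, ab, tx, compute_dg = FALSE)
    want <- oracle_scan(g, ab, tx)
    expect_identical(got$t1, want$t1)
    expect_identical(got$tier, want$tier)
  }
})

test_that("predicted cleavage sits opposite g10 (t1 - 9) and overlaps are kept", {
  g <- paste(sample(c("A", "C", "G", "T"), 26, replace = TRUE),
             collapse = "")
  flank <- paste(rep("A", 94), collapse = "")
  tx <- paste0(flank, revcomp(g), paste(rep("C", 60), collapse = ""))
  s <- scan_transcript(g, 10, tx, compute_dg = FALSE)
  expect_equal(s$t1, 120)
  expect_equal(s$predicted_cleavage, 111)
  # two overlapping qualifying windows are both reported
  set.seed(8)
  g2 <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
              collapse = "")
  tandem <- paste0(revcomp(g2), revcomp(g2), revcomp(g2))
  s2 <- scan_transcript(g2, 10, tandem, compute_dg = FALSE)
  expect_gte(nrow(s2), 3)
})

test_that("random guide-transcript pairs essentially never qualify", {
  set.seed(99)
  g <- paste(sample(c("A", "C", "G", "T"), 28, replace = TRUE),
             collapse = "")
  tx <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
              collapse = "")
  expect_equal(nrow(scan_transcript(g, 1, tx, compute_dg = FALSE)), 0)
})

test_that("seed matching enforces the molecule floor and finds 7-mer sites", {
  set.seed(3)
  g <- paste(sample(c("A", "C", "G", "T"), 27, replace = TRUE),
             collapse = "")
  seed_rc <- revcomp(substr(g, 2, 8))
  utr <- paste0(paste(rep("A", 100), collapse = ""), seed_rc,
                paste(rep("C", 100), collapse = ""))
  tx <- setNames(paste0(paste(rep("G", 300), collapse = ""), utr), "t1")
  utr3 <- data.frame(transcript_id = "t1", start = 301, end = 300 + nchar(utr))
  hit <- seed_targets(setNames(g, "g1"), c(g1 = 1500), tx, utr3)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$match_start, 401)
  expect_equal(hit$t1, 408)
  # guides at or below 1,000 molecules are excluded (strict floor)
  expect_equal(nrow(seed_targets(setNames(g, "g1"), c(g1 = 999), tx, utr3)), 0)
  expect_equal(nrow(seed_targets(setNames(g, "g1"), c(g1 = 1000), tx, utr3)), 0)
})

test_that("seed-site counts in random UTRs follow the (L-6)/4^7 expectation", {
  set.seed(31)
  g <- paste(sample(c("A", "C", "G", "T"), 27, replace = TRUE),
             collapse = "")
  n_utr <- 400; L <- 500
  txs <- setNames(vapply(seq_len(n_utr), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)), paste0("t", seq_len(n_utr)))
  utr3 <- data.frame(transcript_id = names(txs), start = 1, end = L)
  hits <- seed_targets(setNames(g, "g1"), c(g1 = 2000), txs, utr3)
  expected <- n_utr * (L - 6) / 4^7
  expect_lt(abs(nrow(hits) - expected), 5 * sqrt(expected) + 3)
})

test_that("translation candidates need motif, seed, and >= 12 paired in g9-g30", {
  g <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
             collapse = "")
  mk_tx <- function(n_paired_9_30, with_motif = TRUE) {
    paired <- c(2:8, if (n_paired_9_30 > 0) seq(9, 8 + n_paired_9_30))
    win <- vapply(seq_len(30), function(i) {
      b <- substr(revcomp(g), i, i)
      gi <- 30 - i + 1
      if (gi %in% paired) b else chartr("ACGT", "CAAA", b)
    }, character(1))
    motif <- if (with_motif) "ATTTA" else "GGGGG"
    paste0(paste(rep("G", 50), collapse = ""), motif,
           paste(win, collapse = ""), paste(rep("G", 30), collapse = ""))
  }
  run <- function(tx) {
    txs <- setNames(tx, "t1")
    utr3 <- data.frame(transcript_id = "t1", start = 1, end = nchar(tx))
    translation_candidates(setNames(g, "g1"), txs, utr3)
  }
  expect_equal(nrow(run(mk_tx(12))), 1)             # boundary: accepted
  expect_equal(nrow(run(mk_tx(11))), 0)             # one short: rejected
  expect_equal(nrow(run(mk_tx(12, with_motif = FALSE))), 0)
})
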