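## piRNA pool and small RNA read simulation.

#' Generate a piRNA pool with log-spread abundances
#'
#' Species get unique 25-nt prefixes, full lengths of 26-31 nt, locus labels,
#' and per-replicate ppm for the control and mutant genotypes. Control
#' replicate ppm is drawn around a log-normal species mean and renormalised
#' so each replicate sums to 10^6 ppm. In the mutant genotype, species from
#' ablated loci are reduced to an absolute residual below the detection
#' threshold (promoter deletion removes the precursor transcript); the
#' remaining species are renormalised.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list of class \code{pirna_pool}: \code{info} (data.frame with
#'   pirna_id, sequence, prefix, locus), \code{ppm} (list of matrices,
#'   \code{control} and \code{mutant}), \code{mean_ppm} (control means).
#' @export
gen_pirna_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(subseed(cfg$seed, 1L), {
    n <- cfg$n_pirnas
    ## unique 25-nt prefixes with bounded retries
    prefixes <- character(0)
    for (attempt in 1:20) {
      need <- n - length(prefixes)
      if (need == 0L) break
      prefixes <- unique(c(prefixes, random_seq(need, 25L)))
    }
    if (length(prefixes) < n) stop("could not generate unique 25-nt prefixes")
    prefixes <- prefixes[seq_len(n)]
    tails <- vapply(sample(1:6, n, replace = TRUE), function(k) {
      paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
    }, character(1L))
    seqs <- paste0(prefixes, tails)
    loci <- sprintf("locus%02d", sample.int(cfg$n_loci, n, replace = TRUE))
    ## every locus must exist; reassign if sampling missed one
    missing_loci <- setdiff(sprintf("locus%02d", seq_len(cfg$n_loci)), loci)
    if (length(missing_loci)) {
      loci[sample.int(n, length(missing_loci))] <- missing_loci
    }
    ids <- sprintf("pi%03d", seq_len(n))
    mean_raw <- rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)

    draw_reps <- function(base, k) {
      m <- vapply(seq_len(k), function(j) {
        x <- base * rlnorm(n, 0, cfg$rep_cv)
        x / sum(x) * 1e6
      }, numeric(n))
      colnames(m) <- paste0("rep", seq_len(k))
      rownames(m) <- ids
      m
    }
    ctrl <- draw_reps(mean_raw, cfg$n_smallrna_control)
    ## mutant: ablated-locus species fall to an absolute residual (< 0.1 ppm)
    mut_base <- mean_raw
    abl <- loci %in% cfg$ablated_loci
    mut <- vapply(seq_len(cfg$n_smallrna_mutant), function(j) {
      x <- mut_base * rlnorm(n, 0, cfg$rep_cv)
      x[abl] <- 0
      x <- x / sum(x) * 1e6
      x[abl] <- runif(sum(abl), 0, 0.05)
      x
    }, numeric(n))
    colnames(mut) <- paste0("rep", seq_len(cfg$n_smallrna_mutant))
    rownames(mut) <- ids

    pool <- list(info = data.frame(pirna_id = ids, sequence = seqs,
                                   prefix = prefixes, locus = loci,
                                   stringsAsFactors = FALSE),
                 ppm = list(control = ctrl, mutant = mut),
                 mean_ppm = setNames(rowMeans(ctrl), ids))
    class(pool) <- "pirna_pool"
    pool
  })
}

#' Define a spike-in oligo mix
#'
#' An equimolar mix of synthetic RNA oligos used for absolute quantification.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame with \code{id}, \code{sequence}, \code{molecules}.
#' @export
gen_spike_mix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(subseed(cfg$seed, 2L), {
    data.frame(id = sprintf("spike%02d", seq_len(cfg$n_spikes)),
               sequence = vapply(26L + (seq_len(cfg$n_spikes) %% 5L),
                                 function(l) random_seq(1L, l),
                                 character(1L)),
               molecules = rep(cfg$spike_molecules, cfg$n_spikes),
               stringsAsFactors = FALSE)
  })
}

#' Simulate small RNA-seq reads for one replicate
#'
#' Reads have the library structure \code{UMI5(9) + insert + 3' adapter +
#' UMI3(9)}. Species are sampled in proportion to their ppm; inserts show
#' 3'-end heterogeneity (0-2 nt trimmed, never below 25 nt); spike-in reads
#' are added in proportion to the molar mix; and a configurable fraction of
#' exact PCR duplicates is injected.
#'
#' @param pool a \code{pirna_pool}.
#' @param spike_mix data.frame from \code{\link{gen_spike_mix}} (or NULL).
#' @param depth total reads to emit.
#' @param cfg a \code{\link{sim_config}} (duplicate fraction, capture rate).
#' @param genotype \code{"control"} or \code{"mutant"}.
#' @param replicate replicate index (column of the ppm matrix).
#' @param seed seed for this read set.
#' @return character vector of reads.
#' @export
gen_smallrna_reads <- function(pool, spike_mix, depth, cfg,
                               genotype = "control", replicate = 1L,
                               seed = cfg$seed) {
  stopifnot(inherits(pool, "pirna_pool"), depth > 0)
  with_seed(subseed(seed, 100L + replicate +
                      1000L * (genotype == "mutant")), {
    ppm <- pool$ppm[[genotype]][, replicate]
    n_spike <- if (is.null(spike_mix)) integer(0) else {
      rpois(nrow(spike_mix), spike_mix$molecules * cfg$spike_capture)
    }
    n_unique <- max(0L, round(depth * (1 - cfg$dup_frac)) - sum(n_spike))
    counts <- as.vector(rmultinom(1L, n_unique, prob = ppm))
    idx <- rep.int(seq_along(counts), counts)
    seqs <- pool$info$sequence[idx]
    ## 3' heterogeneity: trim 0-2 nt, never below the 25-nt prefix
    trim <- sample(0:2, length(seqs), replace = TRUE)
    trim <- pmin(trim, nchar(seqs) - 25L)
    inserts <- substr(seqs, 1L, nchar(seqs) - trim)
    if (length(n_spike)) {
      inserts <- c(inserts, rep.int(spike_mix$sequence, n_spike))
    }
    m <- length(inserts)
    umi5 <- .random_umis(m, 9L)
    umi3 <- .random_umis(m, 9L)
    reads <- paste0(umi5, inserts, "TGGAATTCTCGGGTGCCAAGG", umi3)
    n_dup <- depth - m
    if (n_dup > 0L && m > 0L) {
      reads <- c(reads, reads[sample.int(m, n_dup, replace = TRUE)])
    }
    sample(reads)
  })
}

## n random UMIs of length k, vectorised
.random_umis <- function(n, k) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * k, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
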