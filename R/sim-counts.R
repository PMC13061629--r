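## RNA-seq / ribosome footprint / GRO-seq count simulation.

#' Simulate count matrices for RNA-seq, ribosome footprints and GRO-seq
#'
#' Negative-binomial counts with log-normal baseline expression. Derepressed
#' targets are multiplied by their derepression fold in the mutant genotype
#' for both simulated alleles (em1, em2). Ribosome footprint means follow the
#' RNA means times a per-transcript translational efficiency that does not
#' change with genotype (the translation null). GRO-seq is returned as a
#' per-gene density with an optional RNA-polymerase pause bump confined to
#' the first 500 bp (see \code{\link{gen_genome_tracks}}).
#'
#' @param truth truth list from \code{\link{gen_transcriptome_with_sites}}.
#' @param transcriptome the transcriptome list.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{rna} and \code{rfp}, each a list of \code{counts}
#'   (features x samples) and \code{samples} (metadata: genotype, allele,
#'   replicate), plus \code{lengths} and \code{baseline} (expected counts).
#' @export
gen_count_matrices <- function(truth, transcriptome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- transcriptome$annotation
  n_tx <- nrow(ann)
  with_seed(subseed(cfg$seed, 5L), {
    base_mu <- rlnorm(n_tx, cfg$count_meanlog, cfg$count_sdlog)
    names(base_mu) <- ann$transcript_id
    ## transcript-level derepression fold: strongest planted fold among its
    ## ablated-locus sites
    fold <- setNames(rep(1, n_tx), ann$transcript_id)
    s <- truth$sites
    if (nrow(s)) {
      dr <- s[s$derepression_fold > 1 &
                s$locus %in% truth$genotypes$mutant, , drop = FALSE]
      if (nrow(dr)) {
        agg <- tapply(dr$derepression_fold, dr$transcript_id, max)
        fold[names(agg)] <- pmax(fold[names(agg)], agg)
      }
    }
    samples <- data.frame(
      sample = c(paste0("ctrl_rep", seq_len(cfg$n_rna_control)),
                 paste0("em1_rep", seq_len(cfg$n_rna_per_allele)),
                 paste0("em2_rep", seq_len(cfg$n_rna_per_allele))),
      genotype = c(rep("control", cfg$n_rna_control),
                   rep("mutant", 2L * cfg$n_rna_per_allele)),
      allele = c(rep("control", cfg$n_rna_control),
                 rep("em1", cfg$n_rna_per_allele),
                 rep("em2", cfg$n_rna_per_allele)),
      stringsAsFactors = FALSE)
    sf <- runif(nrow(samples), 0.7, 1.3)      # modest library-size variation

    draw <- function(mu_vec) {
      m <- vapply(seq_len(nrow(samples)), function(j) {
        mu <- mu_vec * sf[j]
        if (samples$genotype[j] == "mutant") mu <- mu * fold
        rnbinom(n_tx, mu = mu, size = 1 / cfg$nb_dispersion)
      }, numeric(n_tx))
      dimnames(m) <- list(ann$transcript_id, samples$sample)
      storage.mode(m) <- "integer"
      m
    }
    rna <- draw(base_mu)
    te <- rlnorm(n_tx, 0, 0.3)                # per-transcript TE, genotype-null
    rfp <- draw(base_mu * te * 0.5)
    list(rna = list(counts = rna, samples = samples),
         rfp = list(counts = rfp, samples = samples),
         lengths = setNames(ann$length, ann$transcript_id),
         baseline = base_mu, fold = fold, te = te)
  })
}

#' Simulate genomic tracks: GRO-seq coverage, conservation, repeats
#'
#' Lays the simulated genes along a synthetic chromosome (alternating
#' strands) and produces: bedGraph-style GRO-seq coverage with a constant
#' gene-body rate plus a 3x RNA-polymerase pause bump in the first 500 bp;
#' a per-base conservation track over the piRNA origin intervals (guides
#' with functional cleavage targets are drawn from a lower, drifting score
#' distribution than non-target guides, and CDS segments score high); and
#' repeat intervals overlapping a configurable fraction of piRNA origins.
#'
#' Gene-body PolII densities (ppm/kb) are assigned by target class: targets
#' that increase <= 1.25-fold get the highest transcription rates, > 1.25-fold
#' targets intermediate, non-targets lowest - the regime where high
#' transcription masks cleavage.
#'
#' @param truth truth list.
#' @param pool a \code{pirna_pool}.
#' @param transcriptome the transcriptome list.
#' @param cfg a \code{\link{sim_config}}.
#' @param density_ppm_kb named vector of assigned densities for the three
#'   classes (\code{low_change}, \code{high_change}, \code{non_target}).
#' @param repeat_frac_target,repeat_frac_other probability that a target /
#'   non-target guide origin overlaps a repeat.
#' @return list with \code{genes}, \code{gro} (coverage data.frame),
#'   \code{gro_depth}, \code{origins} (piRNA origin intervals),
#'   \code{conservation} (per-base score track), \code{repeats},
#'   \code{assigned_density}.
#' @export
gen_genome_tracks <- function(truth, pool, transcriptome, cfg,
                              density_ppm_kb = c(low_change = 470,
                                                 high_change = 250,
                                                 non_target = 123),
                              repeat_frac_target = 0.41,
                              repeat_frac_other = 0.17) {
  ann <- transcriptome$annotation
  n_tx <- nrow(ann)
  with_seed(subseed(cfg$seed, 6L), {
    gap <- 1000L
    starts <- cumsum(c(0L, head(ann$length + gap, -1L)))
    strand <- rep(c("+", "-"), length.out = n_tx)
    genes <- data.frame(gene_id = ann$transcript_id, chrom = "chrSim",
                        start = starts, end = starts + ann$length,
                        strand = strand, stringsAsFactors = FALSE)
    ## class assignment from the truth table
    s <- truth$sites
    target_tx <- unique(s$transcript_id[s$role == "target"])
    low_tx <- unique(s$transcript_id[s$role == "target" &
                                       s$derepression_fold <= 1.25])
    cls <- ifelse(ann$transcript_id %in% low_tx, "low_change",
                  ifelse(ann$transcript_id %in% target_tx, "high_change",
                         "non_target"))
    dens <- density_ppm_kb[cls] * rlnorm(n_tx, 0, 0.15)
    ## coverage: per-base rate so that body density comes out as assigned;
    ## a 3x pause bump occupies the first 500 bp from the TSS
    gro_depth <- 2e6
    rate <- dens * gro_depth / 1e6 / 1000      # reads per base in the body
    cov <- lapply(seq_len(n_tx), function(i) {
      g <- genes[i, ]
      if (g$strand == "+") {
        data.frame(chrom = g$chrom,
                   start = c(g$start, g$start + 500L),
                   end = c(g$start + 500L, g$end),
                   score = c(rate[i] * 3, rate[i]), stringsAsFactors = FALSE)
      } else {
        data.frame(chrom = g$chrom,
                   start = c(g$start, g$end - 500L),
                   end = c(g$end - 500L, g$end),
                   score = c(rate[i], rate[i] * 3), stringsAsFactors = FALSE)
      }
    })
    gro <- do.call(rbind, cov)

    ## piRNA origins on a separate locus contig, alternating strands
    info <- pool$info
    glen <- nchar(info$sequence)
    ostart <- cumsum(c(0L, head(glen + 100L, -1L)))
    ostrand <- rep(c("+", "-"), length.out = nrow(info))
    origins <- data.frame(pirna_id = info$pirna_id, chrom = "chrLoci",
                          start = ostart, end = ostart + glen,
                          strand = ostrand, stringsAsFactors = FALSE)
    ## conservation: functional-target guides drift; others are conserved
    func_guides <- unique(s$pirna_id[s$cleavage_efficiency >= 0.05])
    base_score <- ifelse(info$pirna_id %in% func_guides, -0.3, 0.4)
    cons <- do.call(rbind, lapply(seq_len(nrow(info)), function(i) {
      p <- seq(origins$start[i], origins$end[i] - 1L)
      data.frame(chrom = "chrLoci", start = p, end = p + 1L,
                 score = rnorm(length(p), base_score[i], 0.2),
                 stringsAsFactors = FALSE)
    }))
    ## CDS-like highly conserved spare region for category sampling
    spare <- max(origins$end) + 1000L
    spare_pos <- seq(spare, spare + 5000L - 1L)
    cons <- rbind(cons, data.frame(chrom = "chrLoci", start = spare_pos,
                                   end = spare_pos + 1L,
                                   score = rnorm(5000L, 2, 0.5),
                                   stringsAsFactors = FALSE))
    ## repeats overlap target-guide origins at the higher rate
    p_rep <- ifelse(info$pirna_id %in% func_guides, repeat_frac_target,
                    repeat_frac_other)
    in_rep <- runif(nrow(info)) < p_rep
    repeats <- origins[in_rep, c("chrom", "start", "end")]
    if (nrow(repeats)) {
      repeats$start <- pmax(0L, repeats$start - 5L)
      repeats$end <- repeats$end + 5L
    }
    list(genes = genes, gro = gro, gro_depth = sum(gro$score *
                                                     (gro$end - gro$start)),
         origins = origins, conservation = cons, repeats = repeats,
         assigned_density = setNames(dens, ann$transcript_id),
         cds_region = data.frame(chrom = "chrLoci", start = spare,
                                 end = spare + 5000L))
  })
}

#' Simulate a burst-kinetics time course
#'
#' Evaluates the burst-and-steady-state model and adds Gaussian noise,
#' truncated at zero.
#'
#' @param k2,k3 rate constants (min^-1), both > 0.
#' @param e_rel relative active-enzyme amount.
#' @param times sampling times in minutes (nonnegative).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed seed.
#' @return data.frame with \code{time} and \code{p_rel}.
#' @export
gen_kinetic_timecourse <- function(k2, k3, e_rel = 1,
                                   times = c(0, 1, 5, 10, 30, 60),
                                   noise_sd = 0, seed = 1L) {
  if (k2 <= 0 || k3 <= 0) stop("k2 and k3 must be positive")
  if (any(times < 0)) stop("times must be nonnegative")
  with_seed(seed, {
    p <- burst_model(times, k2, k3, e_rel)
    if (noise_sd > 0) p <- pmax(0, p + rnorm(length(times), 0, noise_sd))
    data.frame(time = times, p_rel = p)
  })
}
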