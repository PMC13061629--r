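## End-to-end orchestration: simulate -> quantify -> pair -> degradome ->
## differential expression -> annotate -> kinetics, with a consolidated
## report and a reproducibility manifest.

#' Run the full pipeline on a simulated study
#'
#' Generates every input from the configuration, processes small RNA reads
#' into an absolutely quantified piRNA pool, applies the detection/ablation
#' filters, scans for abundance-tiered target sites, evaluates degradome
#' cleavage evidence over all replicate pairings, runs the two-allele
#' differential-expression analysis and the distribution-level tests,
#' annotates transcription rates, conservation and repeat origins, and fits
#' a demonstration kinetic time course. Returns a report plus a manifest
#' (config hash, seed, checksums of any files written).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param out_dir optional directory; when given, the standard plain-text
#'   files (FASTA/FASTQ/TSV/bedGraph/BED/GTF) are written and checksummed.
#' @param smallrna_reads process small RNA-seq at the read level (slowest
#'   stage); when FALSE the simulated per-replicate ppm matrices are used
#'   directly.
#' @param verbose print stage progress.
#' @return object of class \code{pirslice_run}.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, smallrna_reads = TRUE,
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()

  ## --- simulate ---------------------------------------------------------
  say("simulating piRNA pool, transcriptome, degradome, counts")
  pool <- gen_pirna_pool(cfg)
  spikes <- gen_spike_mix(cfg)
  sim <- gen_transcriptome_with_sites(cfg, pool)
  truth <- sim$truth
  degradome <- gen_degradome(truth, pool, sim, cfg)
  counts <- gen_count_matrices(truth, sim, cfg)
  tracks <- gen_genome_tracks(truth, pool, sim, cfg)

  ## --- small RNA quantification ----------------------------------------
  if (smallrna_reads) {
    say("simulating and quantifying small RNA reads")
    read_sets <- list()
    for (r in seq_len(cfg$n_smallrna_control)) {
      read_sets[[paste0("control_rep", r)]] <-
        gen_smallrna_reads(pool, spikes, cfg$smallrna_depth, cfg,
                           "control", r)
    }
    for (r in seq_len(cfg$n_smallrna_mutant)) {
      read_sets[[paste0("mutant_rep", r)]] <-
        gen_smallrna_reads(pool, spikes, cfg$smallrna_depth, cfg,
                           "mutant", r)
    }
    quant <- quantify_replicates(read_sets, spike_seqs = spikes$sequence)
    ppm <- quant$ppm
    ctrl_cols <- paste0("control_rep", seq_len(cfg$n_smallrna_control))
    mut_cols <- paste0("mutant_rep", seq_len(cfg$n_smallrna_mutant))
  } else {
    quant <- NULL
    ppm <- cbind(pool$ppm$control, pool$ppm$mutant)
    rownames(ppm) <- pool$info$prefix      # species keyed by 25-nt prefix
    colnames(ppm) <- c(paste0("control_rep",
                              seq_len(cfg$n_smallrna_control)),
                       paste0("mutant_rep", seq_len(cfg$n_smallrna_mutant)))
    ctrl_cols <- colnames(ppm)[seq_len(cfg$n_smallrna_control)]
    mut_cols <- colnames(ppm)[cfg$n_smallrna_control +
                                seq_len(cfg$n_smallrna_mutant)]
  }
  expressed <- filter_expressed(ppm, ctrl_cols)
  ablated <- classify_ablated(expressed, mut_cols)
  mean_ppm <- rowMeans(expressed[, ctrl_cols, drop = FALSE])
  quant_tab <- cbind(
    data.frame(prefix = rownames(expressed), mean_ppm = mean_ppm,
               ablated = ablated, stringsAsFactors = FALSE),
    absolute_quantify(ppm = mean_ppm, total_per_cell = cfg$total_per_cell,
                      cell_volume = cfg$cell_volume))
  ## map recovered prefixes back to simulated species ids
  idx <- match(quant_tab$prefix, pool$info$prefix)
  quant_tab$pirna_id <- pool$info$pirna_id[idx]
  quant_tab$locus <- pool$info$locus[idx]

  ## --- pairing ----------------------------------------------------------
  say("scanning guide-target complementarity")
  known <- quant_tab[!is.na(quant_tab$pirna_id), , drop = FALSE]
  guides <- setNames(pool$info$sequence[match(known$pirna_id,
                                              pool$info$pirna_id)],
                     known$pirna_id)
  abundances <- setNames(known$mean_ppm, known$pirna_id)
  sites <- scan_transcriptome(guides, abundances, sim$transcripts,
                              compute_dg = FALSE)

  ## --- expression -------------------------------------------------------
  say("differential expression")
  rna <- counts$rna
  lengths <- counts$lengths
  grp_all <- ifelse(rna$samples$genotype == "control", "control", "mutant")
  de_all <- nb_differential(rna$counts, grp_all, lengths)
  allele_de <- lapply(c("em1", "em2"), function(a) {
    sel <- rna$samples$allele %in% c("control", a)
    nb_differential(rna$counts[, sel, drop = FALSE],
                    grp_all[sel], lengths)
  })
  consensus <- intersect_alleles(allele_de[[1L]], allele_de[[2L]])
  te <- translational_efficiency(counts$rfp$counts, rna$counts, grp_all,
                                 lengths)

  ## --- degradome evidence ----------------------------------------------
  say("degradome evidence and target calling")
  signal <- collapse_five_prime(degradome,
                                lib_sizes = setNames(
                                  rep(attr(degradome, "depth"),
                                      length(unique(degradome$replicate))),
                                  unique(degradome$replicate)))
  expr_tab <- data.frame(transcript_id = de_all$feature,
                         log2fc = de_all$log2fc, fdr = de_all$fdr,
                         steady_state = de_all$control_tpm,
                         stringsAsFactors = FALSE)
  ctrl_reps <- paste0("control_rep", seq_len(cfg$n_degradome_control))
  mut_reps <- paste0("mutant_rep", seq_len(cfg$n_degradome_mutant))
  locus_map <- setNames(pool$info$locus, pool$info$pirna_id)
  calls <- NULL
  if (nrow(sites)) {
    calls <- call_targets(sites, locus_map, cfg$ablated_loci, signal,
                          ctrl_reps, mut_reps, expression = expr_tab)
  }

  ## --- distribution-level tests ----------------------------------------
  ks <- list(with_evidence = NULL, without_evidence = NULL)
  if (!is.null(calls)) {
    l2fc_of <- function(tx) expr_tab$log2fc[match(unique(tx),
                                                  expr_tab$transcript_id)]
    abl_called <- l2fc_of(calls$ablated_calls$transcript_id)
    ctl_called <- l2fc_of(calls$control_calls$transcript_id)
    if (length(abl_called) >= 2L && length(ctl_called) >= 2L) {
      ks$with_evidence <- ks_compare(abl_called, ctl_called)
    }
    sites$locus <- locus_map[sites$pirna_id]
    abl_all <- l2fc_of(sites$transcript_id[sites$locus %in%
                                             cfg$ablated_loci])
    ctl_all <- l2fc_of(sites$transcript_id[!sites$locus %in%
                                             cfg$ablated_loci])
    if (length(abl_all) >= 2L && length(ctl_all) >= 2L) {
      ks$without_evidence <- ks_compare(abl_all, ctl_all)
    }
  }

  ## --- annotation -------------------------------------------------------
  say("annotation: PolII density, conservation, repeats")
  dens <- polii_density(tracks$gro, tracks$genes, tracks$gro_depth)
  cons_all <- conservation_profile(tracks$origins, tracks$conservation)
  func_guides <- unique(truth$sites$pirna_id[
    truth$sites$cleavage_efficiency >= 0.05])
  cons_targets <- conservation_profile(
    tracks$origins[tracks$origins$pirna_id %in% func_guides, , drop = FALSE],
    tracks$conservation)
  rep_frac <- list(
    targets = repeat_fraction(
      tracks$origins[tracks$origins$pirna_id %in% func_guides, ,
                     drop = FALSE], tracks$repeats),
    others = repeat_fraction(
      tracks$origins[!tracks$origins$pirna_id %in% func_guides, ,
                     drop = FALSE], tracks$repeats))

  ## --- kinetics demonstration ------------------------------------------
  tc <- gen_kinetic_timecourse(1, 0.05, 0.5, noise_sd = 0.01,
                               seed = subseed(cfg$seed, 7L))
  kin <- fit_burst(tc)

  ## --- evaluation against the planted truth ----------------------------
  truth_targets <- unique(truth$sites[
    truth$sites$cleavage_efficiency >= 0.05 &
      truth$sites$locus %in% cfg$ablated_loci,
    c("pirna_id", "transcript_id", "predicted_cleavage")])
  eval_tab <- NULL
  if (!is.null(calls)) {
    called <- unique(calls$ablated_calls[, c("pirna_id", "transcript_id",
                                             "predicted_cleavage")])
    key <- function(d) paste(d$pirna_id, d$transcript_id,
                             d$predicted_cleavage)
    tp <- sum(key(called) %in% key(truth_targets))
    eval_tab <- list(
      n_called = nrow(called), n_truth = nrow(truth_targets),
      true_positives = tp,
      precision = if (nrow(called)) tp / nrow(called) else NA_real_,
      recall = if (nrow(truth_targets)) tp / nrow(truth_targets) else
        NA_real_)
  }

  report <- list(
    quant = quant_tab, expressed_ppm = expressed, sites = sites,
    de = list(overall = de_all, em1 = allele_de[[1L]],
              em2 = allele_de[[2L]], consensus = consensus, te = te),
    calls = calls, ks = ks,
    permutation_summary = if (!is.null(calls$perm_ablated)) {
      list(median_size = calls$perm_ablated$median_size,
           iqr_size = calls$perm_ablated$iqr_size,
           n_pairings = calls$perm_ablated$n_pairings)
    },
    annotation = list(polii = dens, conservation_all = cons_all,
                      conservation_targets = cons_targets,
                      repeat_fraction = rep_frac),
    kinetics = kin, evaluation = eval_tab, truth = truth)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- .write_outputs(out_dir, pool, spikes, sim, degradome, counts,
                            tracks, report)
  }
  manifest <- list(
    config_hash = .config_hash(cfg), seed = cfg$seed,
    package_version = as.character(utils::packageVersion("piRslice")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = files)
  structure(list(config = cfg, report = report, manifest = manifest),
            class = "pirslice_run")
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(cfg), file = f)
  unname(tools::md5sum(f))
}

.write_outputs <- function(out_dir, pool, spikes, sim, degradome, counts,
                           tracks, report) {
  p <- function(...) file.path(out_dir, ...)
  write_fasta(setNames(pool$info$sequence, pool$info$pirna_id),
              p("guides.fa"))
  write_fasta(sim$transcripts, p("transcripts.fa"))
  write_fasta(setNames(spikes$sequence, spikes$id), p("spikeins.fa"))
  write_tsv(spikes, p("spikeins.tsv"))
  write_tsv(sim$truth$sites, p("truth_sites.tsv"))
  write_tsv(report$quant, p("pirna_pool.tsv"))
  write_tsv(degradome, p("degradome_5p_ends.tsv"))
  write_tsv(as.data.frame(counts$rna$counts), p("rna_counts.tsv"))
  write_tsv(as.data.frame(counts$rfp$counts), p("rfp_counts.tsv"))
  write_tsv(report$sites, p("sites.tsv"))
  if (!is.null(report$calls)) {
    write_tsv(report$calls$ablated_calls, p("target_calls.tsv"))
  }
  write_gtf(tracks$genes, p("genes.gtf"))
  write_bedgraph(tracks$gro, p("gro_coverage.bedgraph"))
  write_bedgraph(tracks$conservation, p("conservation.bedgraph"))
  write_bed(tracks$origins, p("pirna_origins.bed"))
  write_bed(tracks$repeats, p("repeats.bed"))
  fs <- list.files(out_dir, full.names = TRUE)
  checks <- tools::md5sum(fs)
  setNames(unname(checks), basename(fs))
}

#' @export
print.pirslice_run <- function(x, ...) {
  r <- x$report
  cat("piRslice pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  piRNA species kept: ", nrow(r$quant),
      " (", sum(r$quant$ablated), " ablated in mutant)\n", sep = "")
  cat("  qualifying sites: ", nrow(r$sites), "\n", sep = "")
  if (!is.null(r$evaluation)) {
    cat(sprintf("  target calls: %d (precision %.3f, recall %.3f vs %d planted)\n",
                r$evaluation$n_called, r$evaluation$precision,
                r$evaluation$recall, r$evaluation$n_truth))
  }
  if (!is.null(r$permutation_summary)) {
    cat(sprintf("  permutation set size: median %.1f (IQR %.1f-%.1f over %d pairings)\n",
                r$permutation_summary$median_size,
                r$permutation_summary$iqr_size[1L],
                r$permutation_summary$iqr_size[2L],
                r$permutation_summary$n_pairings))
  }
  if (!is.null(r$ks$with_evidence)) {
    cat(sprintf("  KS (log2FC, cleavage evidence required): D = %.3f, p = %.3g\n",
                r$ks$with_evidence$D, r$ks$with_evidence$p))
  }
  if (!is.null(r$ks$without_evidence)) {
    cat(sprintf("  KS (complementarity only): D = %.3f, p = %.3g\n",
                r$ks$without_evidence$D, r$ks$without_evidence$p))
  }
  cat(sprintf("  kinetics fit: k2 = %.3g, k3 = %.3g min^-1\n",
              r$kinetics$coefficients[["k2"]],
              r$kinetics$coefficients[["k3"]]))
  invisible(x)
}
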