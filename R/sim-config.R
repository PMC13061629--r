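## Simulation configuration: the study conditions the generator emulates.

#' Simulation configuration
#'
#' Defines every knob of the synthetic-data generator. Defaults emulate a
#' scaled-down primary-spermatocyte study: ~10^7 piRNAs per cell, 1,800 um^3
#' cell volume, log-spread species abundances, genotype-structured replicates
#' (control vs a double mutant deleting two piRNA loci, with two simulated
#' CRISPR alleles), degradome signal at predicted cleavage coordinates that
#' collapses when the guide's locus is deleted, and negative-binomial count
#' noise. The seed is mandatory: all generators are pure functions of
#' (config, seed).
#'
#' @param seed integer seed (required).
#' @param n_pirnas number of piRNA species.
#' @param n_loci number of piRNA-producing loci.
#' @param ablated_loci locus names deleted in the mutant genotype.
#' @param n_transcripts number of transcripts.
#' @param tx_len_range transcript length range (nt).
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of species
#'   mean abundance before ppm normalisation.
#' @param rep_cv coefficient of variation of per-replicate species abundance
#'   around the species mean.
#' @param total_per_cell total piRNAs per cell (absolute quantification).
#' @param cell_volume cell volume in um^3.
#' @param n_smallrna_control,n_smallrna_mutant small RNA-seq replicates.
#' @param smallrna_depth reads per small RNA library.
#' @param dup_frac fraction of exact PCR duplicates injected into read sets.
#' @param n_spikes,spike_molecules,spike_capture spike-in mix definition:
#'   number of oligos, molecules of each added per sample, and the capture
#'   probability converting molecules to expected deduplicated counts.
#' @param n_targets planted functional cleavage targets (ablated-locus
#'   guides; cleaved, derepressed).
#' @param n_bystander_ablated ablated-locus sites that qualify by
#'   complementarity but are sliced at a negligible rate.
#' @param n_ctrl_cleaved retained-locus ("control piRNA") sites with cleavage
#'   products in both genotypes.
#' @param n_bystander_control retained-locus complementarity-only sites.
#' @param n_seed_only planted seed-only (g2-g8) sites.
#' @param n_decoys near-miss decoy sites (one fewer paired base than the
#'   tier requires).
#' @param efficiency_range cleavage-efficiency range of functional targets.
#' @param bystander_efficiency_max ceiling of the (negligible) slicing
#'   efficiency of bystander sites.
#' @param derepression_per_efficiency derepression fold = 1 +
#'   \code{derepression_per_efficiency} x efficiency.
#' @param degradome_depth degradome library depth per replicate.
#' @param n_degradome_control,n_degradome_mutant degradome replicates.
#' @param degradome_background_frac fraction of the degradome library that is
#'   uniform background over transcript positions.
#' @param degradome_signal_ppm_per_eff cleavage-product abundance (ppm) per
#'   unit cleavage efficiency in guide-retaining genotypes.
#' @param ablation_factor degradome signal reduction in genotypes lacking the
#'   guide's locus (default 100x, not 0, so the "undetectable" filters are
#'   exercised rather than trivialised).
#' @param nb_dispersion negative-binomial dispersion of RNA-seq / ribosome
#'   footprint counts.
#' @param n_rna_control,n_rna_per_allele RNA-seq replicates for the control
#'   and for each mutant allele (em1, em2).
#' @param count_meanlog,count_sdlog log-normal parameters of baseline
#'   transcript expression (expected counts).
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed,
                       n_pirnas = 100L,
                       n_loci = 10L,
                       ablated_loci = c("locus01", "locus02"),
                       n_transcripts = 200L,
                       tx_len_range = c(1200L, 2100L),
                       abundance_meanlog = log(50),
                       abundance_sdlog = 1.5,
                       rep_cv = 0.15,
                       total_per_cell = 1e7,
                       cell_volume = 1800,
                       n_smallrna_control = 4L,
                       n_smallrna_mutant = 4L,
                       smallrna_depth = 1e6,
                       dup_frac = 0.1,
                       n_spikes = 9L,
                       spike_molecules = 1e5,
                       spike_capture = 2e-3,
                       n_targets = 20L,
                       n_bystander_ablated = 130L,
                       n_ctrl_cleaved = 20L,
                       n_bystander_control = 20L,
                       n_seed_only = 10L,
                       n_decoys = 20L,
                       efficiency_range = c(0.05, 0.5),
                       bystander_efficiency_max = 2e-5,
                       derepression_per_efficiency = 4,
                       degradome_depth = 1e7,
                       n_degradome_control = 4L,
                       n_degradome_mutant = 4L,
                       degradome_background_frac = 5e-5,
                       degradome_signal_ppm_per_eff = 40,
                       ablation_factor = 100,
                       nb_dispersion = 0.02,
                       n_rna_control = 4L,
                       n_rna_per_allele = 2L,
                       count_meanlog = log(400),
                       count_sdlog = 0.6) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot_scalar_num(seed, "seed")
  cfg <- list(seed = as.integer(seed), n_pirnas = as.integer(n_pirnas),
              n_loci = as.integer(n_loci), ablated_loci = ablated_loci,
              n_transcripts = as.integer(n_transcripts),
              tx_len_range = as.integer(tx_len_range),
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog, rep_cv = rep_cv,
              total_per_cell = total_per_cell, cell_volume = cell_volume,
              n_smallrna_control = as.integer(n_smallrna_control),
              n_smallrna_mutant = as.integer(n_smallrna_mutant),
              smallrna_depth = smallrna_depth, dup_frac = dup_frac,
              n_spikes = as.integer(n_spikes),
              spike_molecules = spike_molecules,
              spike_capture = spike_capture,
              n_targets = as.integer(n_targets),
              n_bystander_ablated = as.integer(n_bystander_ablated),
              n_ctrl_cleaved = as.integer(n_ctrl_cleaved),
              n_bystander_control = as.integer(n_bystander_control),
              n_seed_only = as.integer(n_seed_only),
              n_decoys = as.integer(n_decoys),
              efficiency_range = efficiency_range,
              bystander_efficiency_max = bystander_efficiency_max,
              derepression_per_efficiency = derepression_per_efficiency,
              degradome_depth = degradome_depth,
              n_degradome_control = as.integer(n_degradome_control),
              n_degradome_mutant = as.integer(n_degradome_mutant),
              degradome_background_frac = degradome_background_frac,
              degradome_signal_ppm_per_eff = degradome_signal_ppm_per_eff,
              ablation_factor = ablation_factor,
              nb_dispersion = nb_dispersion,
              n_rna_control = as.integer(n_rna_control),
              n_rna_per_allele = as.integer(n_rna_per_allele),
              count_meanlog = count_meanlog, count_sdlog = count_sdlog)
  counts <- c("n_pirnas", "n_loci", "n_transcripts", "n_smallrna_control",
              "n_smallrna_mutant", "n_spikes", "n_degradome_control",
              "n_degradome_mutant", "n_rna_control", "n_rna_per_allele")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop("'", nm, "' must be positive")
  }
  if (any(c(cfg$smallrna_depth, cfg$degradome_depth) <= 0)) {
    stop("sequencing depths must be positive")
  }
  if (cfg$n_targets + cfg$n_bystander_ablated + cfg$n_ctrl_cleaved +
        cfg$n_bystander_control + cfg$n_seed_only > cfg$n_transcripts) {
    stop("more planted sites than transcripts")
  }
  if (cfg$dup_frac < 0 || cfg$dup_frac >= 1) stop("dup_frac must be in [0,1)")
  if (length(cfg$ablated_loci) < 1L) stop("need >= 1 ablated locus")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  piRNAs: ", x$n_pirnas, " across ", x$n_loci, " loci; ablated: ",
      paste(x$ablated_loci, collapse = ", "), "\n", sep = "")
  cat("  transcripts: ", x$n_transcripts, "; planted targets: ",
      x$n_targets, " (+", x$n_bystander_ablated + x$n_bystander_control,
      " bystander, ", x$n_ctrl_cleaved, " control-cleaved, ",
      x$n_seed_only, " seed-only, ", x$n_decoys, " decoy)\n", sep = "")
  cat("  small RNA depth ", format(x$smallrna_depth, big.mark = ","),
      "; degradome depth ", format(x$degradome_depth, big.mark = ","),
      "\n", sep = "")
  invisible(x)
}
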