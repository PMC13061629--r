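## Degradome (5'-monophosphate 5'-end) signal simulation.

#' Simulate degradome 5'-end tables per replicate and genotype
#'
#' For every planted site with nonzero cleavage efficiency, 5'-end counts are
#' placed at the predicted cleavage coordinate with Poisson mean proportional
#' to efficiency, reduced by the ablation factor in genotypes lacking the
#' guide's locus. A uniform low-level Poisson background is spread over all
#' transcript positions. Counts are reported per replicate; ppm is count /
#' depth x 1e6.
#'
#' @param truth truth list from \code{\link{gen_transcriptome_with_sites}}.
#' @param pool a \code{pirna_pool}.
#' @param transcriptome the transcriptome list (for transcript lengths).
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame with \code{genotype}, \code{replicate},
#'   \code{transcript_id}, \code{pos}, \code{count}; attribute \code{depth}.
#' @export
gen_degradome <- function(truth, pool, transcriptome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ablated <- truth$genotypes$mutant
  known <- unique(pool$info$locus)
  if (!all(ablated %in% known)) {
    stop("genotype references unknown locus: ",
         paste(setdiff(ablated, known), collapse = ", "))
  }
  ann <- transcriptome$annotation
  sites <- truth$sites
  depth <- cfg$degradome_depth
  ## signal mean (counts) per unit efficiency at this depth
  lam_unit <- cfg$degradome_signal_ppm_per_eff * depth / 1e6
  reps <- list(control = cfg$n_degradome_control,
               mutant = cfg$n_degradome_mutant)
  out <- list()
  with_seed(subseed(cfg$seed, 4L), {
    for (gt in names(reps)) {
      lost <- if (gt == "mutant") ablated else character(0)
      for (r in seq_len(reps[[gt]])) {
        ## planted cleavage products
        if (nrow(sites)) {
          lam <- sites$cleavage_efficiency * lam_unit
          lam[sites$locus %in% lost] <- lam[sites$locus %in% lost] /
            cfg$ablation_factor
          cnt <- rpois(nrow(sites), lam)
          sig <- data.frame(transcript_id = sites$transcript_id,
                            pos = sites$predicted_cleavage, count = cnt,
                            stringsAsFactors = FALSE)
          sig <- sig[sig$count > 0L, , drop = FALSE]
        } else {
          sig <- data.frame(transcript_id = character(0), pos = integer(0),
                            count = integer(0), stringsAsFactors = FALSE)
        }
        ## uniform background over all transcript positions
        n_bg <- rpois(1L, cfg$degradome_background_frac * depth)
        if (n_bg > 0L) {
          total_len <- sum(ann$length)
          flat <- sample.int(total_len, n_bg, replace = TRUE)
          cum <- cumsum(ann$length)
          tx_i <- findInterval(flat - 1L, c(0L, cum), rightmost.closed = TRUE)
          pos <- flat - c(0L, cum)[tx_i]
          bg <- data.frame(transcript_id = ann$transcript_id[tx_i],
                           pos = pos, count = 1L, stringsAsFactors = FALSE)
          sig <- rbind(sig, bg)
        }
        if (nrow(sig)) {
          sig <- stats::aggregate(count ~ transcript_id + pos, data = sig,
                                  FUN = sum)
          sig$genotype <- gt
          sig$replicate <- paste0(gt, "_rep", r)
          out[[length(out) + 1L]] <- sig
        }
      }
    }
  })
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(transcript_id = character(0), pos = integer(0),
               count = integer(0), genotype = character(0),
               replicate = character(0), stringsAsFactors = FALSE)
  }
  res <- res[, c("genotype", "replicate", "transcript_id", "pos", "count")]
  rownames(res) <- NULL
  attr(res, "depth") <- depth
  res
}
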