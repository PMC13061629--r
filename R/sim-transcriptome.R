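## Transcriptome with planted guide-target sites and a machine-readable
## ground truth.

## paired guide positions for each planted pattern; decoys carry one fewer
## paired base than the pattern requires
.pattern_positions <- function(pattern, decoy = FALSE) {
  switch(pattern,
    extensive20 = {
      ## 20 (19 for a decoy) paired within g2-g25, with an unpaired position
      ## inside g6-g14 so no contiguous clause can be satisfied
      n_unpaired <- if (decoy) 5L else 4L
      u1 <- sample(6:14, 1L)
      u_rest <- sample(setdiff(2:25, u1), n_unpaired - 1L)
      sort(setdiff(2:25, c(u1, u_rest)))
    },
    contig_g3g15 = if (decoy) setdiff(3:15, sample(4:14, 1L)) else 3:15,
    contig_g3g16 = if (decoy) setdiff(3:16, sample(4:15, 1L)) else 3:16,
    contig_g4g17 = if (decoy) setdiff(4:17, sample(5:16, 1L)) else 4:17,
    seed_only = 2:8,
    none = integer(0),
    stop("unknown pattern: ", pattern)
  )
}

## construct a target window for `guide` paired exactly at `paired`
.build_window <- function(guide, paired) {
  g <- seq_chars(guide)
  L <- length(g)
  comp <- complement_base(g)
  w <- character(L)                 # w in transcript orientation, 5'->3'
  for (i in seq_len(L)) {
    tpos <- L - i + 1L
    if (i %in% paired) {
      w[tpos] <- comp[i]
    } else {
      w[tpos] <- sample(setdiff(DNA_BASES, comp[i]), 1L)
    }
  }
  paste(w, collapse = "")
}

#' Generate a transcriptome with planted target sites
#'
#' Random-sequence transcripts (with annotated 5'UTR/CDS/3'UTR) carry planted
#' guide-target sites: the site substring is the reverse complement of the
#' guide at exactly the positions its pattern requires and mismatched
#' elsewhere, so each site satisfies its intended clause and fails all
#' stricter ones. Functional targets (ablated-locus guides) get a cleavage
#' efficiency and a derepression fold coupled to it; bystander sites qualify
#' by complementarity but are sliced at a negligible rate; control-guide
#' sites are cleaved but never derepressed (their locus is retained);
#' seed-only and near-miss decoy sites are planted and recorded as well.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param pool a \code{pirna_pool} from \code{\link{gen_pirna_pool}}.
#' @return list with \code{transcripts} (named character vector),
#'   \code{annotation} (per-transcript UTR/CDS spans), and \code{truth}
#'   (list: \code{sites} data.frame and \code{genotypes}, the ablated loci
#'   per simulated genotype).
#' @export
gen_transcriptome_with_sites <- function(cfg, pool) {
  stopifnot(inherits(cfg, "sim_config"), inherits(pool, "pirna_pool"))
  if (nrow(pool$info) == 0L) stop("empty piRNA pool")
  with_seed(subseed(cfg$seed, 3L), {
    n_tx <- cfg$n_transcripts
    lens <- sample(seq(cfg$tx_len_range[1L], cfg$tx_len_range[2L]), n_tx,
                   replace = TRUE)
    tx_ids <- sprintf("tx%04d", seq_len(n_tx))
    txs <- setNames(vapply(lens, function(l) random_seq(1L, l),
                           character(1L)), tx_ids)
    ann <- data.frame(transcript_id = tx_ids, length = lens,
                      utr5_start = 1L, utr5_end = 150L,
                      cds_start = 151L, cds_end = lens - 451L,
                      utr3_start = lens - 450L, utr3_end = lens,
                      stringsAsFactors = FALSE)

    abl_guides <- pool$info$pirna_id[pool$info$locus %in% cfg$ablated_loci]
    ret_guides <- pool$info$pirna_id[!pool$info$locus %in% cfg$ablated_loci]
    if (cfg$n_targets + cfg$n_bystander_ablated > 0L && !length(abl_guides)) {
      stop("no guides from ablated loci; increase n_pirnas or loci overlap")
    }
    if (cfg$n_ctrl_cleaved + cfg$n_bystander_control > 0L &&
          !length(ret_guides)) {
      stop("no guides from retained loci")
    }

    patterns <- c("extensive20", "contig_g3g15", "contig_g3g16",
                  "contig_g4g17")
    roles <- c(rep("target", cfg$n_targets),
               rep("bystander_ablated", cfg$n_bystander_ablated),
               rep("ctrl_cleaved", cfg$n_ctrl_cleaved),
               rep("bystander_control", cfg$n_bystander_control),
               rep("seed_only", cfg$n_seed_only))
    n_sites <- length(roles)
    site_tx <- tx_ids[seq_len(n_sites)]          # one primary site per transcript
    rows <- vector("list", n_sites + cfg$n_decoys)
    occupied <- vector("list", n_tx)             # planted windows per transcript
    names(occupied) <- tx_ids

    pick_guide <- function(pattern_floor, candidates) {
      ## guide must meet the clause's abundance floor
      ok <- candidates[pool$mean_ppm[candidates] >= pattern_floor]
      if (!length(ok)) return(NA_character_)
      sample(ok, 1L)
    }

    plant <- function(tid, gid, pattern, decoy) {
      guide <- pool$info$sequence[pool$info$pirna_id == gid]
      L <- nchar(guide)
      len <- ann$length[ann$transcript_id == tid]
      ## keep the site away from transcript ends; seed-only sites go in the
      ## 3' UTR so miRNA-like searches can find them
      lo <- if (pattern == "seed_only") len - 450L + L else L + 60L
      hi <- len - 60L
      used <- occupied[[tid]]
      for (try in 1:50) {
        t1 <- sample(seq(lo, hi), 1L)
        win <- c(t1 - L + 1L, t1)
        clash <- FALSE
        if (!is.null(used)) {
          for (u in used) {
            if (win[1L] <= u[2L] + 10L && u[1L] <= win[2L] + 10L) clash <- TRUE
          }
        }
        if (!clash) break
        if (try == 50L) stop("transcript too short for requested site: ", tid)
      }
      occupied[[tid]] <<- c(occupied[[tid]], list(win))
      paired <- .pattern_positions(pattern, decoy)
      wseq <- .build_window(guide, paired)
      txs[[tid]] <<- paste0(substr(txs[[tid]], 1L, win[1L] - 1L), wseq,
                            substr(txs[[tid]], win[2L] + 1L, len))
      mask <- pair_mask(guide, wseq)
      tier <- evaluate_tier(mask, pool$mean_ppm[[gid]])
      list(pirna_id = gid, transcript_id = tid, t1 = t1, tier = tier,
           predicted_cleavage = t1 - 9L)
    }

    for (k in seq_len(n_sites)) {
      role <- roles[k]
      pattern <- if (role == "seed_only") "seed_only" else {
        patterns[(k - 1L) %% length(patterns) + 1L]
      }
      floor <- if (pattern == "seed_only") 1 else .TIERS[[pattern]]$min_ppm
      cands <- if (role %in% c("target", "bystander_ablated")) abl_guides
               else ret_guides
      gid <- pick_guide(floor, cands)
      if (is.na(gid)) {            # no guide abundant enough for this clause
        pattern <- "extensive20"
        gid <- pick_guide(1, cands)
        if (is.na(gid)) stop("no guide meets the 1 ppm floor")
      }
      p <- plant(site_tx[k], gid, pattern, decoy = FALSE)
      eff <- switch(role,
        target = runif(1L, cfg$efficiency_range[1L], cfg$efficiency_range[2L]),
        ctrl_cleaved = runif(1L, cfg$efficiency_range[1L],
                             cfg$efficiency_range[2L]),
        bystander_ablated = runif(1L, 0, cfg$bystander_efficiency_max),
        bystander_control = runif(1L, 0, cfg$bystander_efficiency_max),
        seed_only = 0)
      fold <- if (role == "target") {
        1 + cfg$derepression_per_efficiency * eff
      } else 1
      rows[[k]] <- data.frame(
        site_id = sprintf("site%03d", k), pirna_id = p$pirna_id,
        transcript_id = p$transcript_id,
        locus = pool$info$locus[pool$info$pirna_id == p$pirna_id],
        role = role, decoy = FALSE, tier = p$tier, t1 = p$t1,
        predicted_cleavage = p$predicted_cleavage,
        cleavage_efficiency = eff, derepression_fold = fold,
        stringsAsFactors = FALSE)
    }

    ## near-miss decoys: cycle transcripts and patterns; guides from both
    ## locus classes
    if (cfg$n_decoys > 0L) {
      for (d in seq_len(cfg$n_decoys)) {
        tid <- tx_ids[(d - 1L) %% n_tx + 1L]
        pattern <- patterns[(d - 1L) %% length(patterns) + 1L]
        cands <- if (d %% 2L == 0L) abl_guides else ret_guides
        gid <- pick_guide(.TIERS[[pattern]]$min_ppm, cands)
        if (is.na(gid)) gid <- pick_guide(1, c(abl_guides, ret_guides))
        p <- plant(tid, gid, pattern, decoy = TRUE)
        rows[[n_sites + d]] <- data.frame(
          site_id = sprintf("decoy%03d", d), pirna_id = p$pirna_id,
          transcript_id = p$transcript_id,
          locus = pool$info$locus[pool$info$pirna_id == p$pirna_id],
          role = "decoy", decoy = TRUE, tier = p$tier, t1 = p$t1,
          predicted_cleavage = p$predicted_cleavage,
          cleavage_efficiency = 0, derepression_fold = 1,
          stringsAsFactors = FALSE)
      }
    }

    sites <- if (length(rows)) do.call(rbind, rows) else data.frame()
    if (nrow(sites)) {
      bad <- sites$t1 > ann$length[match(sites$transcript_id,
                                         ann$transcript_id)]
      stopifnot(!any(bad))
    }
    list(transcripts = txs, annotation = ann,
         truth = list(sites = sites,
                      genotypes = list(control = character(0),
                                       mutant = cfg$ablated_loci)))
  })
}
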