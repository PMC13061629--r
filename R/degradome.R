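## Degradome cleavage evidence: 5'-end collapsing, detection and fold-change
## filters, replicate-permutation support, fraction cleaved, target calls.

#' Collapse per-read 5'-end records into 5'-monophosphorylated species
#'
#' Reads with the same 5' end are merged: one record per (transcript,
#' position, replicate), with ppm normalised per replicate library.
#'
#' @param end_table data.frame with \code{transcript_id}, \code{pos},
#'   \code{replicate}, and either per-read rows or a \code{count} column;
#'   optionally \code{genotype}.
#' @param lib_sizes optional named vector of library sizes per replicate used
#'   as the ppm denominator; defaults to each replicate's total count.
#' @param tx_lengths optional named vector of transcript lengths; records
#'   with positions outside their transcript are rejected and tallied in the
#'   \code{n_rejected} attribute.
#' @return data.frame with \code{replicate}, \code{transcript_id},
#'   \code{pos}, \code{count}, \code{ppm} (and \code{genotype} if supplied).
#' @export
collapse_five_prime <- function(end_table, lib_sizes = NULL,
                                tx_lengths = NULL) {
  cols <- c("transcript_id", "pos", "replicate")
  if (!all(cols %in% names(end_table))) {
    stop("end_table needs columns: ", paste(cols, collapse = ", "))
  }
  df <- end_table
  if (!"count" %in% names(df)) df$count <- rep(1L, nrow(df))
  n_rejected <- 0L
  if (!is.null(tx_lengths)) {
    len <- tx_lengths[df$transcript_id]
    bad <- is.na(len) | df$pos < 1L | df$pos > len
    n_rejected <- sum(bad)
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) {
    out <- data.frame(replicate = character(0), transcript_id = character(0),
                      pos = integer(0), count = integer(0), ppm = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- n_rejected
    return(out)
  }
  has_gt <- "genotype" %in% names(df)
  f <- if (has_gt) count ~ genotype + replicate + transcript_id + pos else
    count ~ replicate + transcript_id + pos
  agg <- stats::aggregate(f, data = df, FUN = sum)
  totals <- tapply(agg$count, agg$replicate, sum)
  if (is.null(lib_sizes)) {
    lib_sizes <- totals
  } else {
    miss <- setdiff(names(totals), names(lib_sizes))
    if (length(miss)) stop("lib_sizes missing replicates: ",
                           paste(miss, collapse = ", "))
  }
  agg$ppm <- agg$count / as.numeric(lib_sizes[as.character(agg$replicate)]) * 1e6
  agg <- agg[order(agg$replicate, agg$transcript_id, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n_rejected") <- n_rejected
  agg
}

## ppm at exact (transcript, position) for a set of sites, one column per
## replicate; tolerance widens the match window by +/- tol nt
.site_ppm_matrix <- function(signal, sites, replicates, tol = 0L) {
  m <- matrix(0, nrow = nrow(sites), ncol = length(replicates),
              dimnames = list(NULL, replicates))
  for (j in seq_along(replicates)) {
    sub <- signal[signal$replicate == replicates[j], , drop = FALSE]
    if (!nrow(sub)) next
    for (i in seq_len(nrow(sites))) {
      sel <- sub$transcript_id == sites$transcript_id[i] &
        abs(sub$pos - sites$predicted_cleavage[i]) <= tol
      if (any(sel)) m[i, j] <- sum(sub$ppm[sel])
    }
  }
  m
}

#' Cleavage evidence at a predicted site
#'
#' A site is \emph{detected} when the control ppm at the exact predicted
#' coordinate is >= \code{detect_ppm}. For the ablated-guide analysis the
#' site passes when it is detected and the (pseudocounted) control/mutant
#' fold is >= \code{fold}; for the control-guide analysis it passes when it
#' is detected in both genotypes.
#'
#' @param control_ppm,mutant_ppm ppm at the predicted coordinate.
#' @param detect_ppm detection threshold, default 0.1 ppm (inclusive).
#' @param fold required fold decrease, default 8 (inclusive).
#' @param pseudocount added to both ppm values, default 0.01.
#' @param mode \code{"ablated"} (detected + fold) or \code{"both_detected"}.
#' @return list with \code{detected}, \code{fold_change}, \code{passes}.
#' @export
site_evidence <- function(control_ppm, mutant_ppm, detect_ppm = 0.1,
                          fold = 8, pseudocount = 0.01,
                          mode = c("ablated", "both_detected")) {
  mode <- match.arg(mode)
  detected <- control_ppm >= detect_ppm
  fc <- (control_ppm + pseudocount) / (mutant_ppm + pseudocount)
  passes <- if (mode == "ablated") {
    detected & fc >= fold
  } else {
    detected & mutant_ppm >= detect_ppm
  }
  list(detected = detected, fold_change = fc, passes = passes)
}

#' Evaluate cleavage evidence over all replicate pairings
#'
#' Applies \code{\link{site_evidence}} to every (control replicate, mutant
#' replicate) pairing - n_control x n_mutant permutations - and reports the
#' per-pairing target sets, per-site support counts, and the median/IQR of
#' the set sizes.
#'
#' @param signal collapsed degradome signal (\code{\link{collapse_five_prime}}).
#' @param sites data.frame of predicted sites with \code{transcript_id} and
#'   \code{predicted_cleavage} columns.
#' @param control_reps,mutant_reps replicate labels per genotype.
#' @param tol positional tolerance in nt when matching 5' ends to predicted
#'   coordinates (default 0 = exact).
#' @param ... passed to \code{\link{site_evidence}}.
#' @return list with \code{pass} (sites x pairings logical matrix),
#'   \code{support} (per-site counts), \code{set_sizes}, \code{median_size},
#'   \code{iqr_size}, \code{n_pairings}.
#' @export
permutation_calls <- function(signal, sites, control_reps, mutant_reps,
                              tol = 0L, ...) {
  if (length(control_reps) < 1L || length(mutant_reps) < 1L) {
    stop("need >= 1 replicate per genotype")
  }
  ctrl <- .site_ppm_matrix(signal, sites, control_reps, tol)
  mut <- .site_ppm_matrix(signal, sites, mutant_reps, tol)
  pairings <- expand.grid(control = control_reps, mutant = mutant_reps,
                          stringsAsFactors = FALSE)
  pass <- matrix(FALSE, nrow = nrow(sites), ncol = nrow(pairings),
                 dimnames = list(NULL, paste(pairings$control,
                                             pairings$mutant, sep = "|")))
  for (k in seq_len(nrow(pairings))) {
    ev <- site_evidence(ctrl[, pairings$control[k]],
                        mut[, pairings$mutant[k]], ...)
    pass[, k] <- ev$passes
  }
  sizes <- colSums(pass)
  list(pass = pass, support = rowSums(pass), set_sizes = sizes,
       median_size = median(sizes),
       iqr_size = unname(quantile(sizes, c(0.25, 0.75))),
       n_pairings = nrow(pairings),
       control_ppm = ctrl, mutant_ppm = mut)
}

#' Fraction of a target's transcripts that are cleaved
#'
#' Ratio of 3' cleavage-product abundance to the target's steady-state
#' level, on matched units (both ppm of their libraries, or both molecules
#' per cell). Not clipped.
#'
#' @param product_ppm cleavage-product abundance.
#' @param target_steady_state steady-state target abundance (> 0).
#' @return the ratio.
#' @export
fraction_cleaved <- function(product_ppm, target_steady_state) {
  if (any(target_steady_state <= 0)) {
    stop("target steady-state level must be positive")
  }
  product_ppm / target_steady_state
}

#' Call cleavage targets by joining pairing, degradome and expression evidence
#'
#' Splits qualifying sites by guide-locus class (ablated vs retained),
#' enforces exclusivity (a site position also explained by a qualifying
#' retained-locus guide is removed from the ablated-locus set), evaluates
#' degradome evidence over all replicate pairings, and calls sites supported
#' in at least \code{min_support_frac} of the pairings. Expression log2 fold
#' changes are joined per transcript, fraction cleaved is computed from mean
#' control product ppm over steady-state abundance, and targets are
#' classified into <= 1.25-fold vs > 1.25-fold steady-state increase classes
#' (boundary in the <= class).
#'
#' @param sites qualifying sites from \code{\link{scan_transcriptome}}.
#' @param guide_loci named vector mapping piRNA ids to locus labels.
#' @param ablated_loci loci deleted in the mutant genotype.
#' @param signal collapsed degradome signal.
#' @param control_reps,mutant_reps degradome replicate labels.
#' @param expression optional data.frame with \code{transcript_id},
#'   \code{log2fc}, \code{fdr}, \code{steady_state} (control abundance).
#' @param min_support_frac fraction of pairings required, default 0.5.
#' @param tol positional tolerance (nt).
#' @param ... further arguments to \code{\link{site_evidence}}.
#' @return list with \code{ablated_calls} and \code{control_calls}
#'   (data.frames of called sites with support, fraction cleaved, expression
#'   columns and target class), plus the two \code{permutation_calls}
#'   results (\code{perm_ablated}, \code{perm_control}) and
#'   \code{excluded_shared} (sites removed by the exclusivity rule).
#' @export
call_targets <- function(sites, guide_loci, ablated_loci, signal,
                         control_reps, mutant_reps, expression = NULL,
                         min_support_frac = 0.5, tol = 0L, ...) {
  if (!nrow(sites)) stop("no qualifying sites supplied")
  miss <- setdiff(sites$pirna_id, names(guide_loci))
  if (length(miss)) stop("guide without locus assignment: ", miss[1L])
  if (!is.null(expression)) {
    bad <- setdiff(sites$transcript_id, expression$transcript_id)
    if (length(bad)) stop("transcript missing from expression table: ",
                          bad[1L])
  }
  sites$locus <- unname(guide_loci[sites$pirna_id])
  sites$key <- paste(sites$transcript_id, sites$predicted_cleavage)
  abl <- sites[sites$locus %in% ablated_loci, , drop = FALSE]
  ret <- sites[!sites$locus %in% ablated_loci, , drop = FALSE]
  ## exclusivity: ablated-locus sites also explained by a retained guide
  shared <- abl$key %in% ret$key
  excluded <- abl[shared, , drop = FALSE]
  abl <- abl[!shared, , drop = FALSE]

  finish <- function(set, mode) {
    if (!nrow(set)) {
      return(list(calls = set, perm = NULL))
    }
    perm <- permutation_calls(signal, set, control_reps, mutant_reps,
                              tol = tol, mode = mode, ...)
    set$support <- perm$support
    set$n_pairings <- perm$n_pairings
    set$mean_control_ppm <- rowMeans(perm$control_ppm)
    set$mean_mutant_ppm <- rowMeans(perm$mutant_ppm)
    calls <- set[set$support >= min_support_frac * perm$n_pairings, ,
                 drop = FALSE]
    if (!is.null(expression) && nrow(calls)) {
      i <- match(calls$transcript_id, expression$transcript_id)
      calls$log2fc <- expression$log2fc[i]
      calls$fdr <- expression$fdr[i]
      calls$steady_state <- expression$steady_state[i]
      calls$fraction_cleaved <- ifelse(
        calls$steady_state > 0,
        fraction_cleaved(calls$mean_control_ppm,
                         calls$steady_state), NA_real_)
      calls$target_class <- ifelse(2^calls$log2fc > 1.25,
                                   "gt_1.25", "le_1.25")
    }
    rownames(calls) <- NULL
    list(calls = calls, perm = perm)
  }

  a <- finish(abl, "ablated")
  r <- finish(ret, "both_detected")
  list(ablated_calls = a$calls, control_calls = r$calls,
       perm_ablated = a$perm, perm_control = r$perm,
       excluded_shared = excluded)
}
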