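## Guide-target complementarity under abundance-tiered rules.
##
## Conventions: guide positions g1..g30 are counted from the piRNA 5' end;
## the target nucleotide paired to g1 is t1 and pairing is antiparallel, so
## gi pairs transcript position t1 - (i - 1). PIWI slicing cuts the target
## between the nucleotides paired to g10 and g11; the 5' end of the 3'
## cleavage fragment is therefore t1 - 9. Coordinates are 1-based inclusive
## in every user-facing table.

## The four pairing clauses: a site qualifies under a clause when the guide
## meets the clause's abundance floor AND the mask satisfies its pattern.
## The reported tier is the satisfied clause with the lowest floor.
.TIERS <- list(
  extensive20 = list(min_ppm = 1,  type = "count",  from = 2L, to = 25L,
                     min_paired = 20L),
  contig_g3g15 = list(min_ppm = 5,  type = "contig", from = 3L, to = 15L),
  contig_g3g16 = list(min_ppm = 10, type = "contig", from = 3L, to = 16L),
  contig_g4g17 = list(min_ppm = 50, type = "contig", from = 4L, to = 17L)
)

#' Tier definitions for guide-target pairing
#'
#' Returns the abundance-tiered pairing clauses: at >= 1 ppm, >= 20 nt paired
#' within g2-g25; at >= 5 ppm, contiguous pairing g3-g15; at >= 10 ppm,
#' contiguous g3-g16; at >= 50 ppm, contiguous g4-g17.
#'
#' @return named list of clauses (abundance floor in ppm and pattern).
#' @export
pairing_tiers <- function() .TIERS

#' Per-position Watson-Crick complementarity mask
#'
#' \code{mask[i]} is TRUE when guide position gi is the Watson-Crick
#' complement of the target nucleotide it faces in the antiparallel duplex
#' whose t1 is the last base of \code{target_window}. G:U wobble counts as
#' unpaired unless \code{wobble = TRUE}.
#'
#' @param guide guide (piRNA) sequence, 5' to 3'; RNA or DNA alphabet.
#' @param target_window transcript window of the same length, 5' to 3'.
#' @param wobble count G:U pairs as paired (default FALSE).
#' @return logical vector of length \code{min(nchar(guide), 30)}.
#' @export
pair_mask <- function(guide, target_window, wobble = FALSE) {
  g <- norm_seq(guide)
  w <- norm_seq(target_window)
  if (nchar(g) != nchar(w)) stop("window length must equal guide length")
  gc <- seq_chars(g)
  rc <- seq_chars(revcomp(w))   # rc[i] = complement of the base facing gi
  m <- gc == rc
  if (wobble) {
    ## guide G : target U  (target base T -> complement A)
    ## guide U : target G  (complement C)
    m <- m | (gc == "G" & rc == "A") | (gc == "T" & rc == "C")
  }
  m[seq_len(min(length(m), 30L))]
}

#' Assign the pairing tier of a mask given guide abundance
#'
#' The clauses form a disjunction; any clause whose abundance floor the guide
#' meets and whose pattern the mask satisfies qualifies the site. The clause
#' with the lowest floor among those satisfied is reported.
#'
#' @param mask logical complementarity mask (g1 first).
#' @param abundance_ppm guide abundance in ppm.
#' @return tier name, or \code{"none"}.
#' @export
evaluate_tier <- function(mask, abundance_ppm) {
  for (nm in names(.TIERS)) {
    cl <- .TIERS[[nm]]
    if (abundance_ppm < cl$min_ppm) next
    if (length(mask) < cl$to) next
    ok <- if (cl$type == "count") {
      sum(mask[cl$from:cl$to]) >= cl$min_paired
    } else {
      all(mask[cl$from:cl$to])
    }
    if (ok) return(nm)
  }
  "none"
}

## longest contiguous TRUE run in a mask -> c(start, end) in g coordinates
longest_run <- function(mask) {
  r <- rle(mask)
  if (!any(r$values)) return(c(NA_integer_, NA_integer_))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  j <- i[which.max(r$lengths[i])]
  c(starts[j], ends[j])
}

#' Scan a transcript for qualifying guide target sites
#'
#' Every window is evaluated under the abundance-tiered rules; qualifying
#' sites are returned sorted by coordinate. Overlapping qualifying windows
#' are all reported. The predicted cleavage coordinate is the transcript
#' position of the 3'-fragment 5' end (paired to g10), i.e. t1 - 9.
#'
#' @param guide guide sequence (>= 25 nt for the tier patterns).
#' @param abundance_ppm guide abundance in ppm.
#' @param transcript transcript sequence.
#' @param wobble count G:U as paired (default FALSE).
#' @param compute_dg also compute the duplex free energy (default TRUE).
#' @return data.frame with one row per qualifying site: \code{t1},
#'   \code{tier}, \code{paired_g2_g25}, \code{run_start}, \code{run_end},
#'   \code{seed_match}, \code{paired_g9_g30}, \code{predicted_cleavage},
#'   \code{delta_g0}.
#' @export
scan_transcript <- function(guide, abundance_ppm, transcript,
                            wobble = FALSE, compute_dg = TRUE) {
  g <- norm_seq(guide)
  tx <- norm_seq(transcript)
  L <- nchar(g)
  n <- nchar(tx)
  if (n < L) stop("transcript shorter than guide")
  hits <- .scan_positions(g, tx, abundance_ppm, wobble)
  .sites_at(g, abundance_ppm, tx, hits, wobble, compute_dg)
}

## vectorised window scan: returns candidate t1 positions (1-based)
.scan_positions <- function(g, tx, abundance_ppm, wobble) {
  L <- nchar(g)
  n <- nchar(tx)
  gi <- seq_len(min(L, 30L))
  gc <- seq_chars(g)
  txc <- seq_chars(tx)
  comp <- complement_base(gc)
  ## v[[i]][p] = TRUE iff window with t1 = p has gi paired
  v <- vector("list", length(gi))
  for (i in gi) {
    m <- txc == comp[i]
    if (wobble) {
      if (gc[i] == "G") m <- m | txc == "T"
      if (gc[i] == "T") m <- m | txc == "G"
    }
    ## gi faces transcript position p - (i - 1); shift right by i - 1
    v[[i]] <- if (i == 1L) m else c(rep(FALSE, i - 1L), m[seq_len(n - i + 1L)])
  }
  cnt <- Reduce(`+`, v[2:25])
  contig_3_15 <- Reduce(`&`, v[3:15])
  contig_3_16 <- contig_3_15 & v[[16L]]
  contig_4_17 <- Reduce(`&`, v[4:17])
  qual <- rep(FALSE, n)
  if (abundance_ppm >= 1)  qual <- qual | (cnt >= 20L)
  if (abundance_ppm >= 5)  qual <- qual | contig_3_15
  if (abundance_ppm >= 10) qual <- qual | contig_3_16
  if (abundance_ppm >= 50) qual <- qual | contig_4_17
  qual[seq_len(min(L - 1L, n))] <- FALSE   # incomplete windows
  which(qual)
}

## build the site table for candidate t1 positions
.sites_at <- function(g, abundance_ppm, tx, t1s, wobble, compute_dg) {
  L <- nchar(g)
  out <- data.frame(t1 = integer(0), tier = character(0),
                    paired_g2_g25 = integer(0), run_start = integer(0),
                    run_end = integer(0), seed_match = logical(0),
                    paired_g9_g30 = integer(0),
                    predicted_cleavage = integer(0), delta_g0 = numeric(0),
                    stringsAsFactors = FALSE)
  if (!length(t1s)) return(out)
  rows <- lapply(sort(t1s), function(p) {
    win <- substr(tx, p - L + 1L, p)
    m <- pair_mask(g, win, wobble = wobble)
    tier <- evaluate_tier(m, abundance_ppm)
    if (tier == "none") return(NULL)
    run <- longest_run(m)
    hi <- seq(9L, min(length(m), 30L))
    data.frame(t1 = p, tier = tier,
               paired_g2_g25 = sum(m[2:min(25L, length(m))]),
               run_start = run[1L], run_end = run[2L],
               seed_match = all(m[2:8]),
               paired_g9_g30 = sum(m[hi]),
               predicted_cleavage = p - 9L,
               delta_g0 = if (compute_dg) duplex_delta_g(m, g, win) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Scan many guides against many transcripts
#'
#' Applies \code{\link{scan_transcript}} to every guide x transcript pair.
#' Guides below 1 ppm can never qualify and are skipped.
#'
#' @param guides named character vector of guide sequences.
#' @param abundance_ppm named numeric vector of guide abundances (ppm).
#' @param transcripts named character vector of transcript sequences.
#' @param wobble count G:U as paired.
#' @param compute_dg compute duplex free energies for qualifying sites.
#' @return data.frame of sites with \code{pirna_id} and \code{transcript_id}
#'   columns prepended.
#' @export
scan_transcriptome <- function(guides, abundance_ppm, transcripts,
                               wobble = FALSE, compute_dg = TRUE) {
  stopifnot(!is.null(names(guides)), !is.null(names(transcripts)))
  ab <- abundance_ppm[names(guides)]
  res <- list()
  for (gid in names(guides)) {
    if (is.na(ab[[gid]]) || ab[[gid]] < 1) next
    g <- norm_seq(guides[[gid]])
    for (tid in names(transcripts)) {
      tx <- norm_seq(transcripts[[tid]])
      if (nchar(tx) < nchar(g)) next
      hits <- .scan_positions(g, tx, ab[[gid]], wobble)
      if (!length(hits)) next
      s <- .sites_at(g, ab[[gid]], tx, hits, wobble, compute_dg)
      if (nrow(s)) {
        s <- cbind(pirna_id = gid, transcript_id = tid, s,
                   stringsAsFactors = FALSE)
        res[[length(res) + 1L]] <- s
      }
    }
  }
  if (!length(res)) {
    return(data.frame(pirna_id = character(0), transcript_id = character(0),
                      t1 = integer(0), tier = character(0),
                      paired_g2_g25 = integer(0), run_start = integer(0),
                      run_end = integer(0), seed_match = logical(0),
                      paired_g9_g30 = integer(0),
                      predicted_cleavage = integer(0),
                      delta_g0 = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Find miRNA-like seed matches in 3' UTRs
#'
#' For guides above an abundance floor (in molecules per cell), returns 3'UTR
#' windows whose sequence is the perfect Watson-Crick complement of the guide
#' seed (g2-g8).
#'
#' @param guides named character vector of guide sequences.
#' @param molecules named numeric vector, molecules per cell for each guide.
#' @param transcripts named character vector of transcript sequences.
#' @param utr3 data.frame with \code{transcript_id}, \code{start}, \code{end}
#'   (1-based inclusive 3'UTR span on the transcript). Transcripts without a
#'   3'UTR entry are skipped.
#' @param min_molecules abundance floor; guides must exceed it (strict,
#'   default 1000 molecules per cell).
#' @return data.frame with \code{pirna_id}, \code{transcript_id}, \code{t1}
#'   (position paired to g1, one 3' of the seed match), \code{match_start}.
#' @export
seed_targets <- function(guides, molecules, transcripts, utr3,
                         min_molecules = 1000) {
  keep <- names(guides)[!is.na(molecules[names(guides)]) &
                          molecules[names(guides)] > min_molecules]
  res <- list()
  for (gid in keep) {
    g <- norm_seq(guides[[gid]])
    seed_rc <- revcomp(substr(g, 2L, 8L))   # 7-mer on the target strand
    for (tid in names(transcripts)) {
      u <- utr3[utr3$transcript_id == tid, , drop = FALSE]
      if (!nrow(u)) next
      useq <- substr(norm_seq(transcripts[[tid]]), u$start[1L], u$end[1L])
      mpos <- gregexpr(seed_rc, useq, fixed = TRUE)[[1L]]
      if (mpos[1L] < 0L) next
      ## match occupies target positions paired to g8..g2; t1 is one past it
      starts <- as.integer(mpos) + u$start[1L] - 1L
      res[[length(res) + 1L]] <- data.frame(
        pirna_id = gid, transcript_id = tid,
        t1 = starts + 7L, match_start = starts, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(pirna_id = character(0), transcript_id = character(0),
                      t1 = integer(0), match_start = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Candidate translation-activation targets
#'
#' Returns transcripts whose 3' UTR contains at least one occurrence of an
#' RNA-binding-protein motif (e.g. the AU-rich ELAVL1 element) and a site
#' fully paired to the guide seed (g2-g8) with >= 12 additional paired
#' positions in g9-g30.
#'
#' @param guides named character vector of guide sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param utr3 data.frame of 3'UTR spans (see \code{\link{seed_targets}}).
#' @param motif_set character vector of motifs (DNA or RNA alphabet);
#'   default the canonical AU-rich element \code{AUUUA}.
#' @param min_paired_g9_g30 default 12.
#' @param wobble count G:U as paired.
#' @return data.frame of candidates: \code{pirna_id}, \code{transcript_id},
#'   \code{t1}, \code{paired_g9_g30}, \code{n_motifs}.
#' @export
translation_candidates <- function(guides, transcripts, utr3,
                                   motif_set = "ATTTA",
                                   min_paired_g9_g30 = 12L, wobble = FALSE) {
  if (!length(motif_set)) stop("motif_set must be nonempty")
  motif_set <- norm_seq(motif_set)
  res <- list()
  for (tid in names(transcripts)) {
    u <- utr3[utr3$transcript_id == tid, , drop = FALSE]
    if (!nrow(u)) next
    tx <- norm_seq(transcripts[[tid]])
    useq <- substr(tx, u$start[1L], u$end[1L])
    n_mot <- sum(vapply(motif_set, function(m) {
      p <- gregexpr(m, useq, fixed = TRUE)[[1L]]
      if (p[1L] < 0L) 0L else length(p)
    }, integer(1L)))
    if (n_mot == 0L) next
    for (gid in names(guides)) {
      g <- norm_seq(guides[[gid]])
      L <- nchar(g)
      ## seed matches inside the UTR locate candidate t1 positions
      seed_rc <- revcomp(substr(g, 2L, 8L))
      mpos <- gregexpr(seed_rc, useq, fixed = TRUE)[[1L]]
      if (mpos[1L] < 0L) next
      for (s in as.integer(mpos)) {
        t1 <- s + u$start[1L] - 1L + 7L
        if (t1 > nchar(tx) || t1 < L) next
        m <- pair_mask(g, substr(tx, t1 - L + 1L, t1), wobble = wobble)
        hi <- seq(9L, min(length(m), 30L))
        if (all(m[2:8]) && sum(m[hi]) >= min_paired_g9_g30) {
          res[[length(res) + 1L]] <- data.frame(
            pirna_id = gid, transcript_id = tid, t1 = t1,
            paired_g9_g30 = sum(m[hi]), n_motifs = n_mot,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(pirna_id = character(0), transcript_id = character(0),
                      t1 = integer(0), paired_g9_g30 = integer(0),
                      n_motifs = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
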