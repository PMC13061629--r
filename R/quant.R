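## Small RNA-seq processing: adapter/UMI handling, 25-nt prefix grouping,
## detection and ablation filters, and absolute quantification.

#' Convert molecules per cell to intracellular concentration (pM)
#'
#' One molecule in a primary spermatocyte of 1,800 um^3 corresponds to about
#' 1 pM (exactly 1 / (1.8e-12 L x N_A) mol/L = 0.92 pM).
#'
#' @param molecules molecules per cell (numeric vector).
#' @param cell_volume cell volume in cubic micrometres; default 1800.
#' @return concentration in pM.
#' @export
molecules_to_pM <- function(molecules, cell_volume = 1800) {
  if (any(molecules < 0, na.rm = TRUE)) stop("molecules must be >= 0")
  volume_l <- cell_volume * 1e-15      # 1 um^3 = 1e-15 L
  molecules / (volume_l * .N_AVOGADRO) * 1e12
}

#' Convert library ppm to molecules per cell
#'
#' With ~1e7 piRNAs per primary spermatocyte, 1 ppm of the small RNA library
#' corresponds to 10 molecules per cell.
#'
#' @param ppm parts per million of the library.
#' @param total_per_cell total molecules of the class per cell (default 1e7
#'   piRNAs per primary spermatocyte).
#' @return molecules per cell.
#' @export
ppm_to_molecules <- function(ppm, total_per_cell = 1e7) {
  ppm / 1e6 * total_per_cell
}

#' Fraction of cells containing at least one molecule
#'
#' Poisson (default) or negative-binomial model for the cell-to-cell molecule
#' count distribution at a given mean.
#'
#' @param mean_molecules mean molecules per cell (>= 0).
#' @param dispersion optional NB dispersion; when supplied the NB zero
#'   probability \code{dnbinom(0, mu, size = 1/dispersion)} is used.
#' @return probability that a cell contains >= 1 molecule.
#' @export
poisson_detectability <- function(mean_molecules, dispersion = NULL) {
  if (any(mean_molecules < 0)) stop("mean_molecules must be >= 0")
  if (is.null(dispersion)) {
    1 - exp(-mean_molecules)
  } else {
    stopifnot_scalar_num(dispersion, "dispersion")
    if (dispersion <= 0) return(1 - exp(-mean_molecules))
    1 - dnbinom(0L, mu = mean_molecules, size = 1 / dispersion)
  }
}

#' Trim the 3' adapter and collapse PCR duplicates
#'
#' Reads are expected to carry a 9-nt UMI at each end of the insert:
#' \code{UMI5(9) + insert + adapter + UMI3(9)}. The adapter is located by an
#' anchored match of its first 8 nt allowing one mismatch; reads without a
#' match are dropped and tallied. One record is kept per distinct
#' (UMI5, insert, UMI3) triple; inserts outside 14-54 nt are discarded.
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence (default the TruSeq-style small RNA
#'   adapter \code{TGGAATTCTCGGGTGCCAAGG}).
#' @param umi_len UMI length on each side (default 9).
#' @param insert_range keep inserts with lengths in this inclusive range.
#' @return list with \code{inserts} (deduplicated insert sequences),
#'   \code{umi5}, \code{umi3}, and a \code{log} list of tallies
#'   (input, no_adapter, out_of_range, duplicates, kept).
#' @export
trim_and_dedup <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                           umi_len = 9L, insert_range = c(14L, 54L)) {
  n_in <- length(reads)
  if (n_in == 0L) {
    return(list(inserts = character(0), umi5 = character(0),
                umi3 = character(0),
                log = list(input = 0L, no_adapter = 0L, out_of_range = 0L,
                           duplicates = 0L, kept = 0L)))
  }
  reads <- toupper(reads)
  anchor <- substr(adapter, 1L, 8L)
  ## exact anchored match first (covers almost all reads)
  pos <- regexpr(anchor, reads, fixed = TRUE)
  miss <- which(pos < 0L)
  if (length(miss)) {
    ## one mismatch allowed in the 8-nt anchor: try the 8 single-mismatch
    ## patterns as regular expressions with a wildcard at each position
    for (i in seq_len(8L)) {
      pat <- paste0(substr(anchor, 1L, i - 1L), ".",
                    substr(anchor, i + 1L, 8L))
      p2 <- regexpr(pat, reads[miss])
      hit <- p2 > 0L
      if (any(hit)) {
        pos[miss[hit]] <- p2[hit]
        miss <- miss[!hit]
        if (!length(miss)) break
      }
    }
  }
  found <- pos > 0L
  ins_start <- umi_len + 1L
  ins_len <- pos - ins_start                    # insert runs up to adapter
  ok_len <- found & ins_len >= insert_range[1L] & ins_len <= insert_range[2L]
  ## UMI3 follows the adapter
  u3_start <- pos + nchar(adapter)
  has_u3 <- nchar(reads) >= u3_start + umi_len - 1L
  keep <- ok_len & has_u3
  inserts <- substr(reads[keep], ins_start, pos[keep] - 1L)
  umi5 <- substr(reads[keep], 1L, umi_len)
  umi3 <- substr(reads[keep], u3_start[keep], u3_start[keep] + umi_len - 1L)
  key <- paste(umi5, inserts, umi3, sep = "\r")
  dup <- duplicated(key)
  list(inserts = inserts[!dup], umi5 = umi5[!dup], umi3 = umi3[!dup],
       log = list(input = n_in,
                  no_adapter = sum(!found),
                  out_of_range = sum(found & !ok_len),
                  duplicates = sum(dup),
                  kept = sum(!dup)))
}

#' Group inserts by their 5' 25-nt prefix
#'
#' 3' trimming leaves piRNA 3' ends heterogeneous, so species are defined by
#' their first 25 nt. Inserts shorter than 25 nt are excluded from grouping
#' (tallied in the result); ppm is computed over all kept inserts.
#'
#' @param inserts character vector of deduplicated insert sequences (one
#'   replicate).
#' @param total optional library size used as the ppm denominator; defaults
#'   to \code{length(inserts)}.
#' @return data.frame with columns \code{prefix}, \code{count}, \code{ppm},
#'   plus attributes \code{n_short} and \code{total}.
#' @export
group_by_prefix <- function(inserts, total = NULL) {
  long <- nchar(inserts) >= 25L
  if (is.null(total)) total <- length(inserts)
  tab <- table(substr(inserts[long], 1L, 25L))
  out <- data.frame(prefix = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$ppm <- if (total > 0) out$count / total * 1e6 else numeric(nrow(out))
  out <- out[order(-out$count, out$prefix), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_short") <- sum(!long)
  attr(out, "total") <- total
  out
}

#' Keep prefix groups detected in every control replicate
#'
#' A species is considered expressed when its abundance is >= \code{min_ppm}
#' (inclusive) in every control replicate.
#'
#' @param ppm matrix (species x replicates) of ppm values with rownames giving
#'   the 25-nt prefixes.
#' @param control_replicates column names or indices of the control
#'   replicates; defaults to all columns.
#' @param min_ppm detection threshold, default 1 ppm.
#' @return the filtered ppm matrix.
#' @export
filter_expressed <- function(ppm, control_replicates = NULL, min_ppm = 1) {
  if (is.null(dim(ppm))) ppm <- matrix(ppm, ncol = 1L,
                                       dimnames = list(names(ppm), "rep1"))
  if (is.null(control_replicates)) control_replicates <- seq_len(ncol(ppm))
  if (length(control_replicates) < 1L) stop("need >= 1 control replicate")
  sub <- ppm[, control_replicates, drop = FALSE]
  keep <- rowSums(sub >= min_ppm) == ncol(sub)
  ppm[keep, , drop = FALSE]
}

#' Label piRNA species undetectable in mutants
#'
#' A species is ablated when its mean abundance across mutant replicates is
#' <= \code{max_ppm} (inclusive).
#'
#' @param ppm species x replicate ppm matrix (typically from
#'   \code{\link{filter_expressed}}).
#' @param mutant_replicates columns holding the mutant replicates.
#' @param max_ppm undetectable threshold, default 0.1 ppm.
#' @return logical vector named by species: TRUE = ablated, FALSE = retained.
#' @export
classify_ablated <- function(ppm, mutant_replicates, max_ppm = 0.1) {
  sub <- ppm[, mutant_replicates, drop = FALSE]
  m <- rowMeans(sub)
  setNames(m <= max_ppm, rownames(ppm))
}

#' Fit a spike-in calibration
#'
#' Least-squares slope through the origin of deduplicated counts versus
#' molecules added, across the spike-in oligos.
#'
#' @param counts deduplicated read counts per spike-in oligo.
#' @param molecules molecules of each oligo added to the sample.
#' @return list with \code{slope} (counts per molecule) and \code{n_detected}.
#' @export
spike_calibration <- function(counts, molecules) {
  if (length(counts) != length(molecules)) {
    stop("counts and molecules must have the same length")
  }
  det <- counts > 0
  if (sum(det) < 2L) stop("need >= 2 detected spike-in oligos for a fit")
  slope <- sum(counts * molecules) / sum(molecules^2)
  if (slope <= 0) stop("spike-in calibration failed: non-positive slope")
  list(slope = slope, n_detected = sum(det))
}

#' Absolute quantification of piRNA species
#'
#' Two routes are implemented. With a spike-in calibration, molecules per
#' cell = count / slope / cells. Without one, ppm is converted through the
#' total piRNAs-per-cell constant. Concentration in pM follows from the cell
#' volume.
#'
#' @param counts species counts (used by the spike-in route).
#' @param ppm species ppm (used by the ppm route; also reported).
#' @param calibration optional result of \code{\link{spike_calibration}}.
#' @param cells number of cells contributing to the library (spike-in route).
#' @param cell_volume cell volume in um^3, default 1800.
#' @param total_per_cell total piRNAs per cell for the ppm route, default 1e7.
#' @return data.frame with \code{molecules} per cell and \code{pM}.
#' @export
absolute_quantify <- function(counts = NULL, ppm = NULL, calibration = NULL,
                              cells = NULL, cell_volume = 1800,
                              total_per_cell = 1e7) {
  if (!is.null(calibration)) {
    if (is.null(counts)) stop("spike-in route requires counts")
    if (is.null(cells) || cells <= 0) stop("spike-in route requires cells > 0")
    if (is.null(calibration$slope) || calibration$slope <= 0) {
      stop("invalid spike-in calibration")
    }
    molecules <- counts / calibration$slope / cells
  } else {
    if (is.null(ppm)) stop("without a calibration, ppm is required")
    molecules <- ppm_to_molecules(ppm, total_per_cell)
  }
  data.frame(molecules = molecules,
             pM = molecules_to_pM(molecules, cell_volume))
}

#' Quantify a set of small RNA-seq replicates into a piRNA pool
#'
#' Convenience wrapper: trims and deduplicates each replicate, removes reads
#' exactly matching spike-in or blacklist sequences, groups by 25-nt prefix,
#' and assembles a species x replicate ppm matrix. Spike-in counts per
#' replicate are returned for calibration.
#'
#' @param read_sets named list of character vectors (reads per replicate).
#' @param spike_seqs optional character vector of spike-in oligo sequences.
#' @param blacklist optional character vector of sequences to drop (exact
#'   match; e.g. rRNA fragments).
#' @param adapter 3' adapter sequence.
#' @return list with \code{ppm} (matrix), \code{counts} (matrix),
#'   \code{spike_counts} (matrix oligo x replicate), \code{logs}.
#' @export
quantify_replicates <- function(read_sets, spike_seqs = NULL,
                                blacklist = NULL,
                                adapter = "TGGAATTCTCGGGTGCCAAGG") {
  stopifnot(is.list(read_sets), length(read_sets) >= 1L)
  if (is.null(names(read_sets))) {
    names(read_sets) <- paste0("rep", seq_along(read_sets))
  }
  drop_set <- c(spike_seqs, blacklist)
  groups <- list(); spikes <- list(); logs <- list()
  for (r in names(read_sets)) {
    td <- trim_and_dedup(read_sets[[r]], adapter = adapter)
    ins <- td$inserts
    if (!is.null(spike_seqs)) {
      sp <- table(factor(ins[ins %in% spike_seqs], levels = spike_seqs))
      spikes[[r]] <- as.integer(sp)
    }
    if (!is.null(drop_set)) ins <- ins[!(ins %in% drop_set)]
    groups[[r]] <- group_by_prefix(ins)
    logs[[r]] <- td$log
  }
  prefixes <- sort(unique(unlist(lapply(groups, `[[`, "prefix"))))
  ppm <- counts <- matrix(0, nrow = length(prefixes), ncol = length(groups),
                          dimnames = list(prefixes, names(groups)))
  for (r in names(groups)) {
    g <- groups[[r]]
    idx <- match(g$prefix, prefixes)
    ppm[idx, r] <- g$ppm
    counts[idx, r] <- g$count
  }
  spike_counts <- NULL
  if (!is.null(spike_seqs)) {
    spike_counts <- do.call(cbind, spikes)
    rownames(spike_counts) <- names(spike_seqs) %||% spike_seqs
  }
  list(ppm = ppm, counts = counts, spike_counts = spike_counts, logs = logs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
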