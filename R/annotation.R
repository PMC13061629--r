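## Genome-track annotation: PolII density, conservation over piRNA origins,
## repeat-origin fractions. Interval arithmetic through GenomicRanges.
## Track and interval inputs use bedGraph/BED semantics (0-based half-open);
## user-facing guide positions remain 1-based (g2-g30).

.track_gr <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$start + 1L, track$end),
                         score = track$score)
}

#' RNA polymerase II density over gene bodies (ppm per kb)
#'
#' Read coverage over the gene body beyond the first 500 bp from the TSS
#' (strand-aware), normalised by sequencing depth and effective gene length:
#' density = reads / depth x 1e6 / kb. Genes of 500 bp or less are excluded
#' and tallied.
#'
#' @param track coverage data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{score} = reads per base; 0-based half-open).
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @param depth total sequencing depth (reads).
#' @param exclude_bp bases excluded downstream of the TSS, default 500.
#' @return data.frame with \code{gene_id}, \code{density_ppm_kb},
#'   \code{body_reads}, \code{effective_kb}; attribute \code{n_excluded}.
#' @export
polii_density <- function(track, genes, depth, exclude_bp = 500L) {
  short <- genes$end - genes$start <= exclude_bp
  excluded <- genes$gene_id[short]
  g <- genes[!short, , drop = FALSE]
  body_start <- ifelse(g$strand == "+", g$start + exclude_bp, g$start)
  body_end <- ifelse(g$strand == "+", g$end, g$end - exclude_bp)
  body <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(body_start + 1L, body_end))
  cov <- .track_gr(track)
  hits <- GenomicRanges::findOverlaps(body, cov)
  ov <- IRanges::pintersect(body[S4Vectors::queryHits(hits)],
                            cov[S4Vectors::subjectHits(hits)])
  reads <- tapply(GenomicRanges::width(ov) *
                    cov$score[S4Vectors::subjectHits(hits)],
                  factor(S4Vectors::queryHits(hits),
                         levels = seq_along(body)), sum)
  reads[is.na(reads)] <- 0
  eff_kb <- (body_end - body_start) / 1000
  out <- data.frame(gene_id = g$gene_id,
                    density_ppm_kb = as.numeric(reads) / depth * 1e6 / eff_kb,
                    body_reads = as.numeric(reads), effective_kb = eff_kb,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- length(excluded)
  attr(out, "excluded") <- excluded
  out
}

## genomic positions (0-based) of guide positions g_from..g_to for one origin
.g_positions <- function(start, end, strand, g_from, g_to) {
  offs <- seq(g_from, g_to) - 1L
  if (strand == "+") start + offs else end - 1L - offs
}

#' Conservation profile over piRNA genomic origins
#'
#' Looks up per-base scores (e.g. PhyloP) at the genomic bases corresponding
#' to guide positions g2-g30 of each piRNA origin (strand-aware: g1 sits at
#' the interval start on +, at end-1 on -), summarises each piRNA by the
#' median, and the cohort by median and IQR across piRNAs. Origins falling
#' off the track are skipped and tallied.
#'
#' @param origins data.frame with \code{pirna_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand}.
#' @param track per-base score data.frame (\code{chrom}, \code{start},
#'   \code{end}, \code{score}).
#' @param g_from,g_to guide-position window, default g2-g30.
#' @return list with \code{per_pirna} (data.frame pirna_id, median_score),
#'   \code{cohort_median}, \code{cohort_iqr}, \code{n_skipped}.
#' @export
conservation_profile <- function(origins, track, g_from = 2L, g_to = 30L) {
  tg <- .track_gr(track)
  per <- vector("list", nrow(origins))
  skipped <- 0L
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    gt <- min(g_to, o$end - o$start)       # short origins: available positions
    if (gt < g_from) { skipped <- skipped + 1L; next }
    pos <- .g_positions(o$start, o$end, o$strand, g_from, gt)
    q <- GenomicRanges::GRanges(o$chrom, IRanges::IRanges(pos + 1L, pos + 1L))
    hits <- GenomicRanges::findOverlaps(q, tg)
    if (length(hits) < length(q)) { skipped <- skipped + 1L; next }
    sc <- tapply(tg$score[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), mean)
    per[[i]] <- data.frame(pirna_id = o$pirna_id,
                           median_score = median(as.numeric(sc)),
                           stringsAsFactors = FALSE)
  }
  per <- per[!vapply(per, is.null, logical(1L))]
  pp <- if (length(per)) do.call(rbind, per) else {
    data.frame(pirna_id = character(0), median_score = numeric(0))
  }
  list(per_pirna = pp,
       cohort_median = if (nrow(pp)) median(pp$median_score) else NA_real_,
       cohort_iqr = if (nrow(pp)) {
         unname(quantile(pp$median_score, c(0.25, 0.75)))
       } else c(NA_real_, NA_real_),
       n_skipped = skipped)
}

#' Sample random fixed-length segments from annotation regions
#'
#' Draws \code{n} segments of width \code{width} uniformly from the supplied
#' regions (e.g. 29-nt segments from CDS annotation) for use as a
#' conservation-background cohort.
#'
#' @param regions data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open).
#' @param n number of segments.
#' @param width segment width in bp, default 29.
#' @param seed seed.
#' @return data.frame like \code{origins} (ids \code{seg...}, strand "+").
#' @export
sample_random_segments <- function(regions, n, width = 29L, seed = 1L) {
  ok <- regions[regions$end - regions$start >= width, , drop = FALSE]
  if (!nrow(ok)) stop("no region is wide enough")
  with_seed(seed, {
    w <- ok$end - ok$start - width + 1L
    ri <- sample.int(nrow(ok), n, replace = TRUE, prob = w)
    off <- floor(runif(n) * w[ri])
    data.frame(pirna_id = sprintf("seg%05d", seq_len(n)),
               chrom = ok$chrom[ri], start = ok$start[ri] + off,
               end = ok$start[ri] + off + width, strand = "+",
               stringsAsFactors = FALSE)
  })
}

#' Fraction of piRNA origins overlapping repeats
#'
#' @param origins piRNA origin intervals (0-based half-open).
#' @param repeats repeat intervals (\code{chrom}, \code{start}, \code{end}).
#' @param rule \code{"any"} (>= 1 bp overlap, default) or \code{"majority"}
#'   (more than half of the origin inside a repeat).
#' @return fraction in [0, 1].
#' @export
repeat_fraction <- function(origins, repeats, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  if (!nrow(origins)) return(NA_real_)
  if (!nrow(repeats)) return(0)
  og <- GenomicRanges::GRanges(origins$chrom,
                               IRanges::IRanges(origins$start + 1L,
                                                origins$end))
  rg <- GenomicRanges::GRanges(repeats$chrom,
                               IRanges::IRanges(repeats$start + 1L,
                                                repeats$end))
  if (rule == "any") {
    mean(GenomicRanges::countOverlaps(og, rg) > 0L)
  } else {
    hits <- GenomicRanges::findOverlaps(og, rg)
    ov <- IRanges::pintersect(og[S4Vectors::queryHits(hits)],
                              rg[S4Vectors::subjectHits(hits)])
    covered <- tapply(GenomicRanges::width(ov),
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_along(og)), sum)
    covered[is.na(covered)] <- 0
    mean(as.numeric(covered) > GenomicRanges::width(og) / 2)
  }
}
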