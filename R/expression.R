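## Differential transcript abundance (NB Wald test with trended-dispersion
## shrinkage), two-allele intersection, translational efficiency, and the
## distribution-level tests.

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factor: the median across features of the ratio
#' of counts to the feature's geometric mean, computed over features with
#' nonzero counts in all samples.
#'
#' @param counts features x samples matrix of nonnegative counts.
#' @return numeric vector of size factors (one per column).
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use)) {
    stop("no feature has nonzero counts in every sample; ",
         "consider a pseudocount")
  }
  apply(counts[use, , drop = FALSE], 2L, function(cnt) {
    exp(median(log(cnt) - lg[use]))
  })
}

#' Transcripts-per-million from counts and feature lengths
#'
#' Effective length equals the annotated transcript length (no fragment-
#' length correction).
#'
#' @param counts features x samples matrix.
#' @param lengths feature lengths in nt (recycled per column).
#' @return TPM matrix.
#' @export
tpm <- function(counts, lengths) {
  rate <- counts / lengths
  sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' Negative-binomial differential abundance (Wald test)
#'
#' Median-of-ratios normalisation; per-feature method-of-moments dispersion
#' shrunk toward a 1/mean trend; Wald test on the log2 ratio of normalised
#' group means (standard-normal reference); Benjamini-Hochberg FDR.
#' Features below \code{min_tpm} in the control group are excluded before
#' testing (about 10 molecules per cell at 3 TPM).
#'
#' @param counts features x samples matrix.
#' @param group factor/character of length ncol: \code{"control"} or
#'   \code{"mutant"}.
#' @param lengths feature lengths (needed for the TPM floor; NULL disables
#'   the floor).
#' @param min_tpm abundance floor in control, default 3 TPM (inclusive).
#' @param prior_df weight of the dispersion trend, default 10.
#' @param total_per_cell transcripts per cell used to report molecules,
#'   default 3.4e6.
#' @return data.frame: \code{feature}, \code{base_mean} (normalised),
#'   \code{log2fc} (mutant/control), \code{se}, \code{p}, \code{fdr},
#'   \code{control_tpm}, \code{molecules}, \code{dispersion}.
#' @export
nb_differential <- function(counts, group, lengths = NULL, min_tpm = 3,
                            prior_df = 10, total_per_cell = 3.4e6) {
  group <- as.character(group)
  if (!all(group %in% c("control", "mutant"))) {
    stop("group must be 'control' or 'mutant'")
  }
  nc <- sum(group == "control"); nm <- sum(group == "mutant")
  if (nc < 2L || nm < 2L) stop("need >= 2 replicates per group")
  sf <- size_factors(counts)
  q <- sweep(counts, 2L, sf, "/")
  ctrl <- q[, group == "control", drop = FALSE]
  mut <- q[, group == "mutant", drop = FALSE]

  ctl_tpm <- if (!is.null(lengths)) {
    rowMeans(tpm(counts[, group == "control", drop = FALSE], lengths))
  } else rep(NA_real_, nrow(counts))
  keep <- if (!is.null(lengths)) ctl_tpm >= min_tpm else
    rep(TRUE, nrow(counts))

  mc <- rowMeans(ctrl); mm <- rowMeans(mut)
  ## pooled method-of-moments dispersion on normalised counts
  vc <- apply(ctrl, 1L, var); vm <- apply(mut, 1L, var)
  df_c <- nc - 1L; df_m <- nm - 1L
  vpool <- (vc * df_c + vm * df_m) / (df_c + df_m)
  mpool <- (mc * nc + mm * nm) / (nc + nm)
  disp_raw <- pmax((vpool - mpool) / mpool^2, 1e-8)
  ## 1/mean trend fitted on log dispersion, then shrink gene estimates to it
  ok <- keep & mpool > 0 & is.finite(disp_raw)
  trend <- rep(median(disp_raw[ok], na.rm = TRUE), nrow(counts))
  if (sum(ok) >= 10L) {
    fit <- try(lm(log(disp_raw[ok]) ~ I(1 / mpool[ok])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      co <- coef(fit)
      trend <- exp(co[1L] + co[2L] / pmax(mpool, 1e-8))
    }
  }
  w <- (df_c + df_m) / (df_c + df_m + prior_df)
  disp <- exp(w * log(disp_raw) + (1 - w) * log(pmax(trend, 1e-8)))

  ## delta-method variance of log group means under NB(mu = sf*q, disp)
  inv_sf_c <- sum(1 / sf[group == "control"])
  inv_sf_m <- sum(1 / sf[group == "mutant"])
  var_log_c <- (mc * inv_sf_c / nc^2 + disp * mc^2 / nc) / pmax(mc, 1e-8)^2
  var_log_m <- (mm * inv_sf_m / nm^2 + disp * mm^2 / nm) / pmax(mm, 1e-8)^2
  l2fc <- log2(mm / mc)
  se <- sqrt(var_log_c + var_log_m) / log(2)
  stat <- l2fc / se
  p <- 2 * pnorm(-abs(stat))
  p[!keep | mc <= 0 | mm <= 0] <- NA
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  data.frame(feature = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean = mpool, log2fc = l2fc, se = se, p = p, fdr = fdr,
             control_tpm = ctl_tpm,
             molecules = ctl_tpm / 1e6 * total_per_cell,
             dispersion = disp, stringsAsFactors = FALSE)
}

#' Intersect differential calls from two mutant alleles
#'
#' A feature is called only when it is significant (FDR below the threshold)
#' in both alleles with fold changes of the same sign; the reported log2
#' fold change is the smaller in magnitude of the two (the absolute minimum
#' of the alleles).
#'
#' @param de_em1,de_em2 results of \code{\link{nb_differential}} on the same
#'   features.
#' @param max_fdr significance threshold, default 0.01 (strict: FDR < 0.01).
#' @return data.frame of consensus calls with \code{feature}, \code{log2fc}
#'   (minimum-magnitude), \code{log2fc_em1}, \code{log2fc_em2},
#'   \code{fdr_em1}, \code{fdr_em2}, \code{called}.
#' @export
intersect_alleles <- function(de_em1, de_em2, max_fdr = 0.01) {
  if (!identical(de_em1$feature, de_em2$feature)) {
    i <- match(de_em1$feature, de_em2$feature)
    if (anyNA(i)) stop("allele tables cover different features")
    de_em2 <- de_em2[i, , drop = FALSE]
  }
  sig <- !is.na(de_em1$fdr) & !is.na(de_em2$fdr) &
    de_em1$fdr < max_fdr & de_em2$fdr < max_fdr
  same_sign <- sign(de_em1$log2fc) == sign(de_em2$log2fc)
  called <- sig & same_sign
  take1 <- abs(de_em1$log2fc) <= abs(de_em2$log2fc)
  l2fc <- ifelse(take1, de_em1$log2fc, de_em2$log2fc)
  data.frame(feature = de_em1$feature, called = called,
             log2fc = ifelse(called, l2fc, NA_real_),
             log2fc_em1 = de_em1$log2fc, log2fc_em2 = de_em2$log2fc,
             fdr_em1 = de_em1$fdr, fdr_em2 = de_em2$fdr,
             stringsAsFactors = FALSE)
}

#' Translational efficiency and its differential test
#'
#' TE = ribosome-footprint TPM / RNA TPM. The differential test works on the
#' ratio of ratios: log2 dTE = log2FC(RFP) - log2FC(RNA), with the two NB
#' Wald variances added. Features with control ribosome occupancy below
#' \code{min_rfp_tpm} are excluded; features with zero RNA TPM are excluded
#' and tallied.
#'
#' @param rfp,rna count matrices over the same features and sample layout.
#' @param group sample group labels (control/mutant).
#' @param lengths feature lengths.
#' @param min_rfp_tpm ribosome-occupancy floor, default 10 TPM (inclusive).
#' @return data.frame with TE in each group, \code{log2_dte}, \code{se},
#'   \code{p}, \code{fdr}.
#' @export
translational_efficiency <- function(rfp, rna, group, lengths,
                                     min_rfp_tpm = 10) {
  stopifnot(identical(dim(rfp), dim(rna)))
  de_rfp <- nb_differential(rfp, group, lengths, min_tpm = 0)
  de_rna <- nb_differential(rna, group, lengths, min_tpm = 0)
  rfp_tpm <- tpm(rfp, lengths); rna_tpm <- tpm(rna, lengths)
  ctrl <- group == "control"; mut <- group == "mutant"
  te_ctrl <- rowMeans(rfp_tpm[, ctrl, drop = FALSE]) /
    rowMeans(rna_tpm[, ctrl, drop = FALSE])
  te_mut <- rowMeans(rfp_tpm[, mut, drop = FALSE]) /
    rowMeans(rna_tpm[, mut, drop = FALSE])
  keep <- rowMeans(rfp_tpm[, ctrl, drop = FALSE]) >= min_rfp_tpm &
    rowMeans(rna_tpm[, ctrl, drop = FALSE]) > 0 &
    rowMeans(rna_tpm[, mut, drop = FALSE]) > 0
  l2dte <- de_rfp$log2fc - de_rna$log2fc
  se <- sqrt(de_rfp$se^2 + de_rna$se^2)
  stat <- l2dte / se
  p <- 2 * pnorm(-abs(stat))
  p[!keep] <- NA
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  data.frame(feature = de_rfp$feature, te_control = te_ctrl,
             te_mutant = te_mut, log2_dte = l2dte, se = se, p = p,
             fdr = fdr, excluded = !keep, stringsAsFactors = FALSE)
}

#' Two-sample two-tailed Kolmogorov-Smirnov comparison
#'
#' @param x,y numeric vectors (each with >= 2 values).
#' @return list with \code{D} and \code{p}.
#' @export
ks_compare <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each set needs >= 2 values")
  kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Two-tailed Mann-Whitney comparison
#'
#' Exact U distribution for small samples (both groups <= 8 and no ties),
#' normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors.
#' @return list with \code{U}, \code{p}.
#' @export
mw_compare <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  exact <- length(x) <= 8L && length(y) <= 8L &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg correction for a family of tests
#'
#' @param p vector of p values.
#' @return BH-adjusted values (step-up procedure).
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Kruskal-Wallis omnibus test with BH-corrected pairwise follow-up
#'
#' Convenience wrapper sharing the Mann-Whitney machinery: the omnibus
#' Kruskal-Wallis test plus all pairwise two-tailed Mann-Whitney tests with
#' Benjamini-Hochberg correction.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @return list with \code{kw} (htest) and \code{pairwise} (data.frame).
#' @export
kw_with_pairwise <- function(values, groups) {
  groups <- as.factor(groups)
  kw <- kruskal.test(values, groups)
  lv <- levels(groups)
  prs <- utils::combn(lv, 2L)
  res <- apply(prs, 2L, function(pr) {
    mw <- mw_compare(values[groups == pr[1L]], values[groups == pr[2L]])
    c(U = mw$U, p = mw$p)
  })
  pw <- data.frame(group1 = prs[1L, ], group2 = prs[2L, ],
                   U = res["U", ], p = res["p", ],
                   fdr = bh_adjust(res["p", ]), stringsAsFactors = FALSE)
  list(kw = kw, pairwise = pw)
}
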