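#' @import methods
#' @importFrom stats median quantile rnorm rpois rbinom rmultinom rnbinom
#'   runif rlnorm rexp setNames p.adjust pnorm pt ks.test wilcox.test
#'   kruskal.test lm coef predict residuals fitted vcov complete.cases simulate
#'   dnbinom var sd nlminb
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Avogadro constant, 1/mol
.N_AVOGADRO <- 6.02214076e23

#' Reverse complement of DNA-alphabet sequences
#'
#' RNA input (U) is accepted and converted to the DNA alphabet. Vectorised.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  x <- norm_seq(x)
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

## uppercase, U -> T, validate alphabet
norm_seq <- function(x) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("sequence contains characters outside the RNA/DNA alphabet: ",
         x[which(bad)[1L]])
  }
  x
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

## split a sequence into a character vector of bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

## random sequence(s); caller controls the RNG state
random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1L))
}

## derive a child seed from a base seed; stays well below .Machine$integer.max
subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629)
}

## run code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## inclusive-threshold helpers used throughout (thresholds applied as printed)
stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a finite numeric scalar")
  }
}
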