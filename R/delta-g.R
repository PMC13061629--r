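## Nearest-neighbour RNA/RNA duplex free energy.
##
## Watson-Crick stack free energies (kcal/mol, 37 C, 1 M NaCl) from the
## standard nearest-neighbour RNA parameter set. Keys are the guide-strand
## dinucleotide 5'-XY-3' (T stands for U); by strand symmetry the value for
## XY equals that of revcomp(XY).
.NN_STACK <- c(
  AA = -0.93, TT = -0.93,
  AT = -1.10,
  TA = -1.33,
  CT = -2.08, AG = -2.08,
  CA = -2.11, TG = -2.11,
  GT = -2.24, AC = -2.24,
  GA = -2.35, TC = -2.35,
  CG = -2.36,
  GG = -3.26, CC = -3.26,
  GC = -3.42
)

.DG_INIT <- 4.09          # duplex initiation, once per duplex with >= 1 stack
.DG_TERM_AU <- 0.45       # per helix terminus closed by an A:U pair

#' Nearest-neighbour free energy of a guide-target duplex
#'
#' Sums Watson-Crick stack free energies over consecutive paired positions of
#' the mask. A single duplex-initiation term is added when at least one stack
#' exists, terminal A:U helix ends pay the standard penalty, and every
#' unpaired guide position contributes a configurable loop penalty. More
#' negative values mean a more stable duplex.
#'
#' @param mask logical complementarity mask (from \code{\link{pair_mask}}).
#' @param guide guide sequence, 5' to 3'.
#' @param target_window target window (unused beyond validation; the stack
#'   identity is determined by the guide strand for Watson-Crick pairs).
#' @param loop_penalty kcal/mol added per unpaired position (default 0.4).
#' @param terminal_au apply the terminal A:U penalty (default TRUE).
#' @return free energy in kcal/mol.
#' @export
duplex_delta_g <- function(mask, guide, target_window = NULL,
                           loop_penalty = 0.4, terminal_au = TRUE) {
  g <- norm_seq(guide)
  gc <- seq_chars(g)[seq_along(mask)]
  dg <- 0
  n_stack <- 0L
  for (i in seq_len(length(mask) - 1L)) {
    if (mask[i] && mask[i + 1L]) {
      key <- paste0(gc[i], gc[i + 1L])
      dg <- dg + .NN_STACK[[key]]
      n_stack <- n_stack + 1L
    }
  }
  if (n_stack > 0L) {
    dg <- dg + .DG_INIT
    if (terminal_au) {
      ## each maximal paired run of length >= 2 is a helix; its two terminal
      ## pairs pay the penalty when they are A:U (guide base A or U)
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values & r$lengths >= 2L)) {
        for (p in c(starts[j], ends[j])) {
          if (gc[p] %in% c("A", "T")) dg <- dg + .DG_TERM_AU
        }
      }
    }
  }
  dg + loop_penalty * sum(!mask)
}
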