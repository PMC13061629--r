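# Independent brute-force oracles. These restate the definitions from first
# principles (character-by-character loops, full enumeration) and never call
# the implementation paths they check.

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A")

oracle_pair_mask <- function(guide, window) {
  g <- strsplit(chartr("U", "T", toupper(guide)), "")[[1]]
  w <- strsplit(chartr("U", "T", toupper(window)), "")[[1]]
  L <- length(g)
  m <- logical(min(L, 30))
  for (i in seq_along(m)) {
    # gi faces the window base L - i + 1 (antiparallel)
    m[i] <- oracle_complement[[g[i]]] == w[L - i + 1]
  }
  m
}

# literal restatement of the four abundance-tiered clauses
oracle_tier <- function(mask, ppm) {
  if (ppm >= 1 && length(mask) >= 25 && sum(mask[2:25]) >= 20) {
    return("extensive20")
  }
  if (ppm >= 5 && length(mask) >= 15 && all(mask[3:15])) {
    return("contig_g3g15")
  }
  if (ppm >= 10 && length(mask) >= 16 && all(mask[3:16])) {
    return("contig_g3g16")
  }
  if (ppm >= 50 && length(mask) >= 17 && all(mask[4:17])) {
    return("contig_g4g17")
  }
  "none"
}

# exhaustive window scan of one guide against one transcript
oracle_scan <- function(guide, ppm, transcript) {
  L <- nchar(guide)
  n <- nchar(transcript)
  out <- list()
  if (n >= L) {
    for (t1 in L:n) {
      win <- substr(transcript, t1 - L + 1, t1)
      tier <- oracle_tier(oracle_pair_mask(guide, win), ppm)
      if (tier != "none") {
        out[[length(out) + 1]] <- data.frame(t1 = t1, tier = tier,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(t1 = integer(0), tier = character(0))
  }
}

# exact two-tailed Mann-Whitney p by full enumeration of group assignments
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  u_all <- apply(sets, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# max ECDF gap
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# BH step-up restated from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
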