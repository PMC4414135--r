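# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, and
# hand-tabulated formulas.

# Exhaustive hypergeometric upper tail by subset enumeration: locus members
# are items 1..K of N; enumerate all C(N, n) subsets and count those with
# >= k locus members.
oracle_hyper_upper <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Closed-form chi-squared upper tail with 4 df: exp(-x/2) * (1 + x/2)
oracle_chisq4_upper <- function(x) exp(-x / 2) * (1 + x / 2)

# Brute-force Venn classification: for each element of the union, find its
# exact membership pattern and tally.
oracle_venn <- function(sets) {
  k <- length(sets)
  un <- unique(unlist(sets))
  out <- integer(0)
  for (r in seq_len(k)) {
    for (idx in utils::combn(k, r, simplify = FALSE)) {
      cnt <- 0L
      for (el in un) {
        memb <- vapply(sets, function(s) el %in% s, TRUE)
        if (all(memb[idx]) && !any(memb[-idx][seq_len(k - r)])) cnt <- cnt + 1L
      }
      out[paste(names(sets)[idx], collapse = "&")] <- cnt
    }
  }
  out
}

# Hand log-rank tabulation over pooled distinct event times (standard
# observed-minus-expected with hypergeometric variance).
oracle_logrank <- function(timeA, eventA, timeB, eventB) {
  times <- sort(unique(c(timeA[eventA == 1], timeB[eventB == 1])))
  OmE <- 0; V <- 0
  for (t in times) {
    n1 <- sum(timeA >= t); n2 <- sum(timeB >= t); nt <- n1 + n2
    d1 <- sum(timeA == t & eventA == 1)
    d2 <- sum(timeB == t & eventB == 1)
    dt <- d1 + d2
    OmE <- OmE + d1 - dt * n1 / nt
    if (nt > 1)
      V <- V + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  OmE^2 / V
}

# Independent SAM d-statistic for a 2-vs-2 contrast
oracle_sam_d <- function(m, tIdx, cIdx, s0) {
  mt <- rowMeans(m[, tIdx, drop = FALSE])
  mc <- rowMeans(m[, cIdx, drop = FALSE])
  ss <- rowSums((m[, tIdx, drop = FALSE] - mt)^2) +
    rowSums((m[, cIdx, drop = FALSE] - mc)^2)
  s <- sqrt(((1 / length(tIdx) + 1 / length(cIdx)) /
               (length(tIdx) + length(cIdx) - 2)) * ss)
  (mt - mc) / (s + s0)
}

# Small deterministic panel fixture
tiny_panel <- function() {
  mirPanel(data.frame(
    mir_id = sprintf("m%02d", 1:10),
    chrom = c(rep("chr14", 4), rep("chr2", 6)),
    start = seq(1000, by = 1000, length.out = 10),
    end = seq(1020, by = 1000, length.out = 10),
    locus_label = c(rep("14q32", 4), rep("", 6))))
}
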