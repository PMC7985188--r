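# Independent brute-force oracles used to check the package's primitives.

# step-up FDR adjustment: sort, scale by m/i, cumulative min from the
# largest, cap at 1
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# upper-tail hypergeometric probability by explicit enumeration of all
# 2x2 tables with the observed margins
enumerateUpperTail <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  mass <- exp(lchoose(c1, xs) + lchoose(n - c1, r1 - xs) - lchoose(n, r1))
  sum(mass[xs >= a])
}

# AUC as the mean pairwise concordance over all positive-negative pairs
enumerateAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(conc)
}

# plug-in MI from an explicitly tabulated joint histogram
bruteForceMi <- function(xb, yb, nBins) {
  n <- length(xb)
  mi <- 0
  for (i in seq_len(nBins)) for (j in seq_len(nBins)) {
    pij <- sum(xb == i & yb == j) / n
    if (pij > 0) {
      pi_ <- sum(xb == i) / n
      pj_ <- sum(yb == j) / n
      mi <- mi + pij * log2(pij / (pi_ * pj_))
    }
  }
  mi
}
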