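# equal-frequency binning; deterministic tie handling via first-occurrence
# ranks (ties may be split across bins, which is documented behaviour)
.equalFreqBins <- function(x, nBins) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * nBins / n)
}

# plug-in MI (bits) from two bin vectors in 1..nBins
.miFromBins <- function(xb, yb, nBins) {
  n <- length(xb)
  joint <- tabulate((xb - 1L) * nBins + yb, nbins = nBins * nBins) / n
  px <- tabulate(xb, nbins = nBins) / n
  py <- tabulate(yb, nbins = nBins) / n
  nz <- joint > 0
  pxy <- outer(px, py)
  # joint is filled column-major as (x, y); outer(px, py) matches t() layout
  pr <- as.vector(t(pxy))
  sum(joint[nz] * log2(joint[nz] / pr[nz]))
}

#' Mutual information between two expression vectors
#'
#' Plug-in mutual-information estimate (bits) after discretizing each
#' vector into `nBins` equal-frequency bins, with a permutation p-value
#' from `nPerm` random relabelings of `y`. A constant vector carries no
#' information: MI 0, p 1.
#'
#' @param x,y numeric vectors of equal length >= 8.
#' @param nBins number of equal-frequency bins (default 3).
#' @param nPerm number of permutations for the p-value (default 999; 0
#'   skips the permutation test, `permutation_p` is then `NA`).
#' @param seed integer seed for the permutations.
#' @return a list with `mi` (bits), `permutation_p` and `n_bins`.
#' @examples
#' x <- seq_len(10)
#' mutualInformation(x, x, nBins = 2, nPerm = 99)$mi  # 1 bit
#' @export
mutualInformation <- function(x, y, nBins = 3L, nPerm = 999L, seed = 1L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 8L) stop("at least 8 observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("'x' and 'y' must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(mi = 0, permutation_p = 1, n_bins = as.integer(nBins)))
  xb <- .equalFreqBins(x, nBins)
  yb <- .equalFreqBins(y, nBins)
  mi <- .miFromBins(xb, yb, nBins)
  p <- NA_real_
  if (nPerm > 0L) {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(nPerm)) {
      if (.miFromBins(xb, yb[sample.int(length(yb))], nBins) >= mi)
        hits <- hits + 1L
    }
    p <- (1 + hits) / (nPerm + 1)
  }
  list(mi = mi, permutation_p = p, n_bins = as.integer(nBins))
}
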