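#' Remove low-variance features
#'
#' Drops features whose variance across all samples, on the `log2(v + 1)`
#' scale, falls below a threshold. With `minVariance = NULL` (default) the
#' threshold is the 5% quantile of the per-feature variances, i.e. the
#' bottom 5% of features by variance are removed.
#'
#' @param m a [LabeledExpression-class] object.
#' @param minVariance nonnegative variance threshold (log2 scale), or
#'   `NULL` for the bottom-5%-quantile policy.
#' @return a [LabeledExpression-class] with the retained features, original
#'   order preserved.
#' @export
lowVarianceFilter <- function(m, minVariance = NULL) {
  stopifnot(is(m, "LabeledExpression"))
  v <- log2(exprValues(m) + 1)
  rowVar <- .rowVars(v)
  if (is.null(minVariance)) {
    thr <- quantile(rowVar, 0.05, names = FALSE)
    keep <- rowVar > thr | rowVar >= max(rowVar)
  } else {
    if (minVariance < 0) stop("'minVariance' must be >= 0")
    keep <- rowVar >= minVariance
  }
  if (!any(keep))
    stop("low-variance filter removed every feature; lower the threshold")
  m[keep, ]
}

.rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

# vectorised Welch two-sample t-test on the rows of a matrix
.rowWelch <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- .rowVars(x[, idx1, drop = FALSE])
  v2 <- .rowVars(x[, idx2, drop = FALSE])
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # identical groups: zero difference, no evidence
  degenerate <- !is.finite(tstat)
  p[degenerate & abs(m1 - m2) < .Machine$double.eps^0.5] <- 1
  p[degenerate & abs(m1 - m2) >= .Machine$double.eps^0.5] <- 0
  list(logFc = m1 - m2, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate, capped
#' at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.04, 0.03, 0.005))
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numbers in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential expression between basal and normal samples
#'
#' Per feature, the log2 fold change is the mean of `log2(v + 1)` over
#' basal samples minus the mean over normal samples; a two-sided p-value
#' comes from Welch's t-test (default) or the Wilcoxon rank-sum test on the
#' same transformed values, adjusted across all tested features by
#' Benjamini-Hochberg. A feature is called differentially expressed when
#' `|logFC| > logfcThreshold` and its (by default adjusted) p-value is
#' below `alpha`.
#'
#' @param m a [LabeledExpression-class] object with both classes present
#'   (>= 2 samples each).
#' @param logfcThreshold absolute log2-fold-change threshold (default 1).
#' @param alpha significance level (default 0.01).
#' @param method `"welch_t"` (default) or `"wilcoxon"`.
#' @param useAdjusted apply `alpha` to the BH-adjusted p-value (default
#'   `TRUE`) or to the raw p-value.
#' @return a data.frame (one row per feature, input order) with columns
#'   `gene_id`, `log_fc`, `p_value`, `adj_p`, `is_deg`.
#' @export
degTest <- function(m, logfcThreshold = 1, alpha = 0.01,
                    method = c("welch_t", "wilcoxon"),
                    useAdjusted = TRUE) {
  stopifnot(is(m, "LabeledExpression"))
  method <- match.arg(method)
  cls <- sampleClass(m)
  idxB <- which(cls == "basal")
  idxN <- which(cls == "normal")
  if (length(idxB) < 2L || length(idxN) < 2L)
    stop("both classes must be present with >= 2 samples")
  x <- log2(exprValues(m) + 1)
  if (method == "welch_t") {
    res <- .rowWelch(x, idxB, idxN)
    logFc <- res$logFc; p <- res$p
  } else {
    logFc <- rowMeans(x[, idxB, drop = FALSE]) -
      rowMeans(x[, idxN, drop = FALSE])
    p <- apply(x, 1L, function(r)
      wilcox.test(r[idxB], r[idxN], exact = FALSE)$p.value)
    p[!is.finite(p)] <- 1
  }
  adj <- bhAdjust(p)
  crit <- if (useAdjusted) adj else p
  data.frame(gene_id = rownames(x), log_fc = unname(logFc),
             p_value = unname(p), adj_p = unname(adj),
             is_deg = unname(abs(logFc) > logfcThreshold & crit < alpha),
             stringsAsFactors = FALSE)
}
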