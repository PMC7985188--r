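#' @rdname exprValues
#' @export
setMethod("exprValues", "LabeledExpression", function(x)
  SummarizedExperiment::assay(x, "expr"))

#' @rdname sampleClass
#' @export
setMethod("sampleClass", "LabeledExpression", function(x)
  setNames(SummarizedExperiment::colData(x)$class, colnames(x)))

#' @rdname sampleClass
#' @export
setMethod("sampleClass", "PairFeatureMatrix", function(x)
  x@labels[colnames(x@scores)])

#' @rdname geneSets
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname pathwayIds
#' @export
setMethod("pathwayIds", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname targetEdges
#' @export
setMethod("targetEdges", "MirnaTargetMap", function(x) x@edges)

#' @export
setMethod("length", "MirnaTargetMap", function(x) length(x@edges))

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "gene sets\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes:", min(sz), "-", max(sz), "genes\n")
  }
  if (nzchar(object@sourceNote))
    cat("  source:", object@sourceNote, "\n")
})

#' @export
setMethod("show", "MirnaTargetMap", function(object) {
  cat("MirnaTargetMap:", length(object@edges), "miRNAs,",
      sum(lengths(object@edges)), "edges\n")
})

#' @export
setMethod("show", "PairFeatureMatrix", function(object) {
  cat("PairFeatureMatrix:", nrow(object@scores), "pathway pairs x",
      ncol(object@scores), "samples\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(object@labels)),
      table(object@labels)), collapse = ", "), "\n")
})

#' @export
setMethod("show", "MirnaNetwork", function(object) {
  cat("MirnaNetwork:", nrow(object@pairs), "pathway pairs,",
      nrow(object@mirnas), "miRNAs\n")
  if (nrow(object@mirnas)) {
    top <- utils::head(object@mirnas, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s  DC=%d  fisher_p=%.3g  (%s)\n", top$mirna_id[i],
          top$degree_centrality[i], top$fisher_p[i],
          top$predicted_direction[i]))
  }
})

#' Selected pathway pairs of a network
#' @param x a [MirnaNetwork-class] object.
#' @return data.frame with columns pathway1, pathway2, pair_id.
#' @export
networkPairs <- function(x) {
  stopifnot(is(x, "MirnaNetwork"))
  x@pairs
}

#' miRNA summary table of a network
#' @param x a [MirnaNetwork-class] object.
#' @return data.frame (mirna_id, degree_centrality, fisher_p,
#'   predicted_direction), ordered by decreasing degree centrality.
#' @export
networkMirnas <- function(x) {
  stopifnot(is(x, "MirnaNetwork"))
  x@mirnas
}

#' Mutual-information edges of a network
#' @param x a [MirnaNetwork-class] object.
#' @return data.frame (mirna_id, gene_id, mi_bits, perm_p).
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "MirnaNetwork"))
  x@edges
}

#' @rdname degreeCentrality
#' @export
setMethod("degreeCentrality", "list", function(x) {
  if (!length(x)) return(0L)
  sum(vapply(x, function(pair) {
    stopifnot(length(pair) == 2L)
    length(unique(pair[[1L]])) + length(unique(pair[[2L]]))
  }, integer(1)))
})

#' @rdname degreeCentrality
#' @export
setMethod("degreeCentrality", "MirnaNetwork", function(x)
  setNames(x@mirnas$degree_centrality, x@mirnas$mirna_id))
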