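#' Expression values of a LabeledExpression object
#' @param x a [LabeledExpression-class] object.
#' @return numeric matrix, features x samples.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Per-sample class labels
#' @param x a [LabeledExpression-class] or [PairFeatureMatrix-class] object.
#' @return named character vector, `"basal"` or `"normal"` per sample.
#' @export
setGeneric("sampleClass", function(x) standardGeneric("sampleClass"))

#' Gene sets of a collection
#' @param x a [GeneSetCollection-class] object.
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Pathway identifiers of a collection
#' @param x a [GeneSetCollection-class] object.
#' @return character vector of pathway ids.
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' miRNA-to-target edges
#' @param x a [MirnaTargetMap-class] object.
#' @return named list of character vectors of target gene ids.
#' @export
setGeneric("targetEdges", function(x) standardGeneric("targetEdges"))

#' Degree centrality
#'
#' For one miRNA, the number of genes it regulates within the selected
#' coupled pathways, counted once per pathway slot per pair: a gene that
#' appears under both pathways of a pair, or under several pairs,
#' contributes once for each slot it appears in. This is the arithmetic
#' behind the published worked example (42 for miR-365 across two coupled
#' pairs of 15+6 and 6+15 genes; 12 for miR-135b across one pair of 6+6).
#'
#' @param x for the list method, the regulated genes of one miRNA: a list
#'   with one element per pair, each a list of two character vectors (genes
#'   under pathway 1 and under pathway 2). For the network method, a
#'   [MirnaNetwork-class] object.
#' @return integer count (list method), or a named integer vector per miRNA
#'   (network method).
#' @examples
#' degreeCentrality(list(list(c("A", "B"), c("B", "C", "D"))))
#' @export
setGeneric("degreeCentrality", function(x) standardGeneric("degreeCentrality"))
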