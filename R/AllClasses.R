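#' Labeled expression matrix
#'
#' A features-by-samples matrix of nonnegative normalized expression values
#' with a binary per-sample class label (`"basal"` or `"normal"`), stored as
#' a [SummarizedExperiment::SummarizedExperiment] with one assay named
#' `"expr"` and a `class` column in `colData`. Used for both the mRNA and
#' the miRNA layer.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @export
setClass("LabeledExpression", contains = "SummarizedExperiment")

.validLabeledExpression <- function(object) {
  msg <- character()
  if (!identical(SummarizedExperiment::assayNames(object), "expr"))
    msg <- c(msg, "exactly one assay named 'expr' is required")
  v <- SummarizedExperiment::assay(object, "expr")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!is.numeric(v) || any(!is.finite(v)))
    msg <- c(msg, "expression values must be finite numbers")
  else if (any(v < 0))
    msg <- c(msg, "expression values must be nonnegative")
  cls <- SummarizedExperiment::colData(object)$class
  if (is.null(cls) || anyNA(cls) || !all(cls %in% c("basal", "normal")))
    msg <- c(msg, "every sample needs a class label in {basal, normal}")
  if (length(msg)) msg else TRUE
}
setValidity("LabeledExpression", .validLabeledExpression)

#' Construct a LabeledExpression object
#'
#' @param values numeric matrix, features x samples, with row and column
#'   names; nonnegative normalized expression values.
#' @param labels named character vector mapping every sample id to
#'   `"basal"` or `"normal"` (extra names are ignored).
#' @return a [LabeledExpression-class] object.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' le <- LabeledExpression(m, c(s1 = "basal", s2 = "normal"))
#' sampleClass(le)
#' @export
LabeledExpression <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("'values' must have sample ids as column names")
  missing <- setdiff(colnames(values), names(labels))
  if (length(missing))
    stop("no class label for sample(s): ", paste(missing, collapse = ", "))
  cd <- S4Vectors::DataFrame(
    class = unname(labels[colnames(values)]),
    row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), colData = cd)
  methods::new("LabeledExpression", se)
}

#' Collection of named gene sets
#'
#' Named pathways, each a set (character vector, deduplicated) of gene
#' identifiers. Gene identifiers are opaque case-sensitive strings; no
#' alias resolution is attempted.
#'
#' @slot sets named list of character vectors; names are pathway ids.
#' @slot sourceNote free-text provenance note.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", sourceNote = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
      msg <- c(msg, "pathway ids must be present and unique")
    if (!all(vapply(s, is.character, logical(1))))
      msg <- c(msg, "gene sets must be character vectors")
    else if (any(lengths(s) == 0L))
      msg <- c(msg, "gene sets must be nonempty")
  }
  if (length(msg)) msg else TRUE
})

#' @param sets named list of character vectors of gene ids.
#' @param sourceNote optional provenance string.
#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets = list(), sourceNote = "") {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  methods::new("GeneSetCollection", sets = sets, sourceNote = sourceNote)
}

#' Bipartite miRNA-to-target map
#'
#' Maps each miRNA id to the set of gene ids it is predicted to target.
#' Empty target sets are not stored.
#'
#' @slot edges named list of character vectors; names are miRNA ids.
#' @export
setClass("MirnaTargetMap", representation(edges = "list"))

setValidity("MirnaTargetMap", function(object) {
  e <- object@edges
  msg <- character()
  if (length(e)) {
    if (is.null(names(e)) || anyDuplicated(names(e)))
      msg <- c(msg, "miRNA ids must be present and unique")
    if (any(lengths(e) == 0L))
      msg <- c(msg, "empty target sets must not be stored")
  }
  if (length(msg)) msg else TRUE
})

#' @param edges named list of character vectors of target gene ids.
#' @rdname MirnaTargetMap-class
#' @export
MirnaTargetMap <- function(edges = list()) {
  edges <- lapply(edges, function(g) unique(as.character(g)))
  edges <- edges[lengths(edges) > 0L]
  methods::new("MirnaTargetMap", edges = edges)
}

#' Pathway-pair feature matrix
#'
#' Per-sample discriminating scores for every unordered pair of pathways,
#' pairs as rows (pathway1 < pathway2 lexicographically), samples as
#' columns, with sample class labels.
#'
#' @slot pairs data.frame with columns pathway1, pathway2, pair_id.
#' @slot scores numeric matrix pairs x samples.
#' @slot labels named character vector of sample classes.
#' @export
setClass("PairFeatureMatrix",
  representation(pairs = "data.frame", scores = "matrix",
                 labels = "character"))

setValidity("PairFeatureMatrix", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("pathway1", "pathway2", "pair_id") %in% names(p)))
    msg <- c(msg, "pairs needs columns pathway1, pathway2, pair_id")
  else {
    if (any(p$pathway1 >= p$pathway2))
      msg <- c(msg, "pairs must satisfy pathway1 < pathway2")
    if (anyDuplicated(p$pair_id))
      msg <- c(msg, "pair ids must be unique")
    if (!identical(rownames(object@scores), p$pair_id))
      msg <- c(msg, "score rownames must equal pair_id")
  }
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (!identical(sort(names(object@labels)), sort(colnames(object@scores))))
    msg <- c(msg, "labels must cover exactly the score columns")
  if (length(msg)) msg else TRUE
})

#' miRNA-pathway-pair network
#'
#' The selected pathway pairs together with the miRNAs attached to them,
#' the genes each miRNA regulates inside each pair, the per-miRNA degree
#' centrality and Fisher p-value, and the supporting mutual-information
#' edges.
#'
#' @slot pairs data.frame of selected pairs (pathway1, pathway2, pair_id).
#' @slot mirnas data.frame with columns mirna_id, degree_centrality,
#'   fisher_p, predicted_direction, ordered by decreasing degree centrality.
#' @slot regulatedGenes per miRNA, a list mapping pair_id to
#'   `list(pathway1 = <genes>, pathway2 = <genes>)`.
#' @slot edges data.frame (mirna_id, gene_id, mi_bits, perm_p) of retained
#'   mutual-information links.
#' @export
setClass("MirnaNetwork",
  representation(pairs = "data.frame", mirnas = "data.frame",
                 regulatedGenes = "list", edges = "data.frame"))
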