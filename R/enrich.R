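#' One-sided Fisher exact test for a 2x2 table
#'
#' Upper-tail hypergeometric probability `P(X >= a)` for the table
#' `[[a, b], [c, d]]` with fixed margins — the enrichment direction: how
#' likely is an overlap at least as large as the observed one.
#'
#' @param a,b,c,d nonnegative integer cell counts; `a` is the overlap cell.
#' @return the one-sided p-value.
#' @examples
#' fisherExactOneSided(5, 0, 0, 5)  # 1 / choose(10, 5)
#' @export
fisherExactOneSided <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0))
    stop("cell counts must be nonnegative")
  if (sum(counts) == 0) stop("table margin must be positive")
  # drawing the a+b items of row 1 from a population with a+c successes
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Pathway enrichment of differentially expressed genes
#'
#' For each gene set, tests over-representation of DEGs with a one-sided
#' Fisher exact test on the 2x2 table (DEG in pathway, DEG outside, pathway
#' non-DEG, remaining universe), adjusts p-values across pathways by
#' Benjamini-Hochberg, and flags pathways with adjusted p below `alpha` as
#' enriched.
#'
#' The gene universe is, by default, the tested genes that appear in at
#' least one pathway (`universePolicy = "in_pathways"`); alternatively all
#' tested genes (`"all_tested"`). Pathways with fewer than `minSetSize`
#' genes in the universe are excluded (with a message).
#'
#' @param deg a DEG table from [degTest()].
#' @param sets a [GeneSetCollection-class].
#' @param universePolicy `"in_pathways"` (default) or `"all_tested"`.
#' @param alpha adjusted-p threshold for enrichment (default 0.01).
#' @param minSetSize minimum pathway size within the universe (default 3).
#' @return a data.frame with one row per tested pathway: `pathway_id`,
#'   `n_pathway_genes_in_universe`, `n_deg_in_pathway`, `p_value`, `adj_p`,
#'   `is_enriched`.
#' @export
enrichPathways <- function(deg, sets,
                           universePolicy = c("in_pathways", "all_tested"),
                           alpha = 0.01, minSetSize = 3L) {
  stopifnot(is.data.frame(deg), is(sets, "GeneSetCollection"))
  universePolicy <- match.arg(universePolicy)
  setList <- geneSets(sets)
  tested <- deg$gene_id
  universe <- switch(universePolicy,
    in_pathways = intersect(tested, unique(unlist(setList,
                                                  use.names = FALSE))),
    all_tested = tested)
  if (!length(universe)) stop("empty gene universe")
  degGenes <- intersect(deg$gene_id[deg$is_deg], universe)
  inUniverse <- lapply(setList, intersect, universe)
  small <- names(setList)[lengths(inUniverse) < minSetSize]
  if (length(small))
    message("excluding ", length(small),
            " pathway(s) with < ", minSetSize, " genes in the universe")
  keep <- setdiff(names(setList), small)
  if (!length(keep))
    stop("no pathway has >= ", minSetSize, " genes in the universe")
  nU <- length(universe)
  nD <- length(degGenes)
  res <- do.call(rbind, lapply(keep, function(pw) {
    pwGenes <- inUniverse[[pw]]
    a <- length(intersect(degGenes, pwGenes))
    b <- nD - a
    c_ <- length(pwGenes) - a
    d <- nU - a - b - c_
    data.frame(pathway_id = pw,
               n_pathway_genes_in_universe = length(pwGenes),
               n_deg_in_pathway = a,
               p_value = fisherExactOneSided(a, b, c_, d),
               stringsAsFactors = FALSE)
  }))
  res$adj_p <- bhAdjust(res$p_value)
  res$is_enriched <- res$adj_p < alpha
  rownames(res) <- NULL
  res
}
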