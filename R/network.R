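#' miRNA-gene links by mutual information
#'
#' For every candidate pair — a miRNA and one of its mapped target genes
#' that lies inside the network gene set — computes the mutual information
#' between the miRNA's and the gene's expression over the samples shared by
#' the two layers (tumor samples only by default, since the network is
#' tumor-specific) and keeps links whose permutation p-value is below
#' `miThresholdP` (optionally after BH adjustment across candidate links).
#'
#' Candidates are enumerated in lexicographic (miRNA, gene) order and each
#' link's permutation stream is seeded from `seed` plus its position, so
#' results do not depend on input ordering.
#'
#' @param mirnaM,mrnaM [LabeledExpression-class] objects for the miRNA and
#'   mRNA layer; tumor sample ids shared between them are used.
#' @param targets a [MirnaTargetMap-class].
#' @param networkGenes character vector of genes in the selected
#'   pathway-pair network.
#' @param miThresholdP link retention threshold on the permutation p
#'   (default 0.05).
#' @param nBins,nPerm passed to [mutualInformation()].
#' @param tumorOnly compute MI on shared tumor samples only (default
#'   `TRUE`) or on all shared samples.
#' @param adjust BH-adjust permutation p-values across candidate links
#'   before thresholding (default `FALSE`).
#' @param seed integer seed.
#' @return a list with `links` (data.frame: mirna_id, gene_id, mi_bits,
#'   perm_p, retained) and `supported` (named list: per miRNA, the genes of
#'   its retained links).
#' @export
mirnaGeneLinks <- function(mirnaM, mrnaM, targets, networkGenes,
                           miThresholdP = 0.05, nBins = 3L, nPerm = 999L,
                           tumorOnly = TRUE, adjust = FALSE, seed = 1L) {
  stopifnot(is(mirnaM, "LabeledExpression"), is(mrnaM, "LabeledExpression"),
            is(targets, "MirnaTargetMap"))
  shared <- intersect(colnames(mirnaM), colnames(mrnaM))
  if (tumorOnly) {
    cls <- sampleClass(mirnaM)
    shared <- shared[cls[shared] == "basal"]
  }
  if (length(shared) < 8L)
    stop("need >= 8 shared ", if (tumorOnly) "tumor " else "",
         "samples between the miRNA and mRNA layers")
  edges <- targetEdges(targets)
  mirnas <- sort(intersect(names(edges), rownames(mirnaM)))
  cand <- do.call(rbind, lapply(mirnas, function(m) {
    genes <- sort(intersect(intersect(edges[[m]], networkGenes),
                            rownames(mrnaM)))
    if (!length(genes)) return(NULL)
    data.frame(mirna_id = m, gene_id = genes, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || !nrow(cand)) {
    return(list(links = data.frame(mirna_id = character(),
                                   gene_id = character(),
                                   mi_bits = numeric(), perm_p = numeric(),
                                   retained = logical()),
                supported = list()))
  }
  miX <- log2(exprValues(mirnaM)[, shared, drop = FALSE] + 1)
  geX <- log2(exprValues(mrnaM)[, shared, drop = FALSE] + 1)
  res <- vapply(seq_len(nrow(cand)), function(i) {
    r <- mutualInformation(miX[cand$mirna_id[i], ], geX[cand$gene_id[i], ],
                           nBins = nBins, nPerm = nPerm,
                           seed = seed + i)
    c(r$mi, r$permutation_p)
  }, numeric(2))
  cand$mi_bits <- res[1L, ]
  cand$perm_p <- res[2L, ]
  p <- if (adjust) bhAdjust(cand$perm_p) else cand$perm_p
  cand$retained <- p < miThresholdP
  kept <- cand[cand$retained, , drop = FALSE]
  supported <- lapply(split(kept$gene_id, kept$mirna_id), sort)
  list(links = cand, supported = supported)
}

#' Fisher test for miRNA over-representation in the network
#'
#' One-sided Fisher exact p for over-representation of a miRNA's
#' MI-supported targets among the network genes, against the gene
#' universe: 2x2 table (supported targets in network, targets outside
#' network, network genes not targeted, rest of universe).
#'
#' @param supportedGenes the miRNA's MI-supported genes (within the
#'   network).
#' @param mirnaTargets all mapped targets of the miRNA.
#' @param networkGenes genes of the selected pathway-pair network (must be
#'   a subset of `universe`).
#' @param universe the gene universe.
#' @return the one-sided p-value.
#' @export
mirnaFisher <- function(supportedGenes, mirnaTargets, networkGenes,
                        universe) {
  if (!length(universe)) stop("empty gene universe")
  networkGenes <- intersect(networkGenes, universe)
  mirnaTargets <- intersect(mirnaTargets, universe)
  a <- length(intersect(supportedGenes, networkGenes))
  b <- length(setdiff(mirnaTargets, networkGenes))
  c_ <- length(setdiff(networkGenes, mirnaTargets))
  d <- length(universe) - a - b - c_
  fisherExactOneSided(a, b, c_, max(d, 0L))
}

#' Assemble the miRNA-pathway-pair network
#'
#' Attaches miRNAs whose Fisher p-value is below `alphaMirna` to the
#' selected pathway pairs via their MI-supported genes, computes each
#' miRNA's degree centrality (genes counted once per pathway slot per
#' pair), and annotates the predicted regulation direction from the sign
#' of the miRNA's mean tumor-minus-normal expression difference
#' (log2(v + 1) scale).
#'
#' @param ranking the `ranking` data.frame from [runMccv()] (rows with
#'   `selected == TRUE` define the network pairs).
#' @param links the result of [mirnaGeneLinks()].
#' @param fisherP named numeric vector of per-miRNA Fisher p-values (as
#'   from [mirnaFisher()]).
#' @param sets the [GeneSetCollection-class] defining pathway membership.
#' @param mirnaM the miRNA [LabeledExpression-class] (for the direction).
#' @param alphaMirna miRNA admission threshold on the Fisher p (default
#'   0.05).
#' @return a [MirnaNetwork-class] object; empty miRNA table if no miRNA
#'   passes (a message is emitted).
#' @export
buildNetwork <- function(ranking, links, fisherP, sets, mirnaM,
                         alphaMirna = 0.05) {
  stopifnot(is.data.frame(ranking), is(sets, "GeneSetCollection"),
            is(mirnaM, "LabeledExpression"))
  pairs <- ranking[ranking$selected,
                   c("pathway1", "pathway2", "pair_id"), drop = FALSE]
  if (!nrow(pairs)) stop("ranking contains no selected pairs")
  rownames(pairs) <- NULL
  setList <- geneSets(sets)

  admitted <- names(fisherP)[fisherP < alphaMirna]
  admitted <- intersect(admitted, names(links$supported))
  if (!length(admitted))
    message("no miRNA passes the Fisher threshold; network has pairs only")

  cls <- sampleClass(mirnaM)
  x <- log2(exprValues(mirnaM) + 1)
  meanDiff <- rowMeans(x[, cls == "basal", drop = FALSE]) -
    rowMeans(x[, cls == "normal", drop = FALSE])

  regulated <- list()
  rows <- lapply(admitted, function(m) {
    supp <- links$supported[[m]]
    perPair <- lapply(seq_len(nrow(pairs)), function(i) list(
      pathway1 = intersect(supp, setList[[pairs$pathway1[i]]]),
      pathway2 = intersect(supp, setList[[pairs$pathway2[i]]])))
    names(perPair) <- pairs$pair_id
    regulated[[m]] <<- perPair
    dc <- degreeCentrality(unname(perPair))
    data.frame(mirna_id = m, degree_centrality = dc,
               fisher_p = unname(fisherP[m]),
               predicted_direction = if (meanDiff[m] >= 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  mirnas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), degree_centrality = integer(),
               fisher_p = numeric(), predicted_direction = character(),
               stringsAsFactors = FALSE)
  if (nrow(mirnas)) {
    ord <- order(-mirnas$degree_centrality, mirnas$fisher_p,
                 mirnas$mirna_id)
    mirnas <- mirnas[ord, , drop = FALSE]
    rownames(mirnas) <- NULL
  }
  linkTab <- links$links
  edges <- if (nrow(linkTab))
    linkTab[linkTab$retained & linkTab$mirna_id %in% mirnas$mirna_id,
            c("mirna_id", "gene_id", "mi_bits", "perm_p"), drop = FALSE]
  else data.frame(mirna_id = character(), gene_id = character(),
                  mi_bits = numeric(), perm_p = numeric())
  rownames(edges) <- NULL
  methods::new("MirnaNetwork", pairs = pairs, mirnas = mirnas,
               regulatedGenes = regulated, edges = edges)
}
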