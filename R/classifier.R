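#' Per-sample pathway activity
#'
#' For one gene set, the mean over its genes of per-gene z-scores of
#' `log2(v + 1)` expression, z-scored across all samples. Genes absent
#' from the matrix are ignored; genes with zero variance are dropped (a
#' set left with no variable gene scores 0 everywhere).
#'
#' @param m a [LabeledExpression-class] object.
#' @param set character vector of gene ids.
#' @param pathwayId optional id used in error messages.
#' @return named numeric vector of activities, one per sample.
#' @export
pathwayActivity <- function(m, set, pathwayId = "<set>") {
  stopifnot(is(m, "LabeledExpression"))
  genes <- intersect(set, rownames(m))
  if (!length(genes))
    stop("no gene of pathway ", pathwayId, " is present in the matrix")
  x <- log2(exprValues(m)[genes, , drop = FALSE] + 1)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  keep <- sdv > 0
  if (!any(keep))
    return(setNames(rep(0, ncol(x)), colnames(x)))
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  colMeans(z)
}

#' Discriminating score of a pathway pair
#'
#' Per-sample scalar summarizing the joint state of two pathways. The
#' default metric is the difference of their mean z-score activities
#' (a stand-in with the required shape — one scalar per sample per pair;
#' the metric is isolated behind this interface so an alternative can be
#' swapped in). `"product"` multiplies the activities instead.
#'
#' @param m a [LabeledExpression-class] object.
#' @param setA,setB character vectors of gene ids.
#' @param metric `"difference"` (default) or `"product"`.
#' @param idA,idB optional pathway ids for error messages.
#' @return named numeric vector of pair scores, one per sample.
#' @export
pairScore <- function(m, setA, setB, metric = c("difference", "product"),
                      idA = "<A>", idB = "<B>") {
  metric <- match.arg(metric)
  aA <- pathwayActivity(m, setA, idA)
  aB <- pathwayActivity(m, setB, idB)
  switch(metric, difference = aA - aB, product = aA * aB)
}

#' Score matrix over all pathway pairs
#'
#' Builds the [PairFeatureMatrix-class] of discriminating scores for every
#' unordered pair of the given pathways (pathway1 < pathway2
#' lexicographically; pair id `"pathway1|pathway2"`).
#'
#' @param m a [LabeledExpression-class] object.
#' @param sets a [GeneSetCollection-class].
#' @param pathways pathway ids to pair up (default: all in `sets`).
#' @param metric passed to [pairScore()].
#' @return a [PairFeatureMatrix-class] object.
#' @export
pairFeatureMatrix <- function(m, sets, pathways = pathwayIds(sets),
                              metric = c("difference", "product")) {
  stopifnot(is(m, "LabeledExpression"), is(sets, "GeneSetCollection"))
  metric <- match.arg(metric)
  pathways <- sort(unique(pathways))
  if (length(pathways) < 2L)
    stop("at least two pathways are required to form pairs")
  setList <- geneSets(sets)
  missing <- setdiff(pathways, names(setList))
  if (length(missing))
    stop("unknown pathway id(s): ", paste(missing, collapse = ", "))
  # activities once per pathway, pairs by subtraction/product
  act <- t(vapply(pathways, function(pw)
    pathwayActivity(m, setList[[pw]], pw), numeric(ncol(m))))
  comb <- t(combn(pathways, 2L))
  pairs <- data.frame(pathway1 = comb[, 1L], pathway2 = comb[, 2L],
                      pair_id = paste(comb[, 1L], comb[, 2L], sep = "|"),
                      stringsAsFactors = FALSE)
  scores <- matrix(NA_real_, nrow(pairs), ncol(m),
                   dimnames = list(pairs$pair_id, colnames(m)))
  for (i in seq_len(nrow(pairs))) {
    a <- act[pairs$pathway1[i], ]; b <- act[pairs$pathway2[i], ]
    scores[i, ] <- if (metric == "difference") a - b else a * b
  }
  methods::new("PairFeatureMatrix", pairs = pairs, scores = scores,
               labels = sampleClass(m))
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance: the probability that a random positive
#' (`"basal"`) sample outranks a random negative one, ties counted 1/2.
#' With `directionFree = TRUE` returns `max(u, 1 - u)`, appropriate when
#' the orientation of the score is arbitrary (as for pathway-pair scores,
#' whose sign depends on the lexicographic pathway order).
#'
#' @param scores numeric vector.
#' @param labels vector with two classes; `"basal"`/`TRUE`/`1` is positive.
#' @param directionFree return `max(u, 1 - u)` (default `FALSE`).
#' @return the AUC in \[0, 1\].
#' @examples
#' aucScore(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
aucScore <- function(scores, labels, directionFree = FALSE) {
  pos <- labels %in% c("basal", TRUE, 1)
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  u <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  if (directionFree) max(u, 1 - u) else u
}

.fitPairAuc <- function(trainScore, trainLab, testScore, testLab,
                        classifier, nTrees) {
  if (classifier == "random_forest") {
    yTrain <- factor(trainLab, levels = c("normal", "basal"))
    rf <- randomForest(x = data.frame(score = trainScore), y = yTrain,
                       ntree = nTrees)
    # honest training performance: out-of-bag class votes
    trainAuc <- aucScore(rf$votes[, "basal"], trainLab)
    prob <- predict(rf, newdata = data.frame(score = testScore),
                    type = "prob")[, "basal"]
    testAuc <- aucScore(prob, testLab)
  } else {
    uTrain <- aucScore(trainScore, trainLab)
    trainAuc <- max(uTrain, 1 - uTrain)
    orient <- if (uTrain >= 0.5) 1 else -1
    testAuc <- aucScore(orient * testScore, testLab)
  }
  c(train = trainAuc, test = testAuc)
}

#' Monte Carlo cross-validation over pathway pairs
#'
#' Repeats `nBootstraps` times: balance the classes by downsampling the
#' majority class to the minority count (without replacement), split the
#' balanced pool into training (`trainFrac`, default 60%) and testing
#' sets stratified by class, fit a classifier per pathway pair on that
#' pair's score alone, and record its training and testing AUC. Within each
#' bootstrap the `topK` pairs by training AUC are noted; the final ranking
#' orders pairs by how often they reached a per-bootstrap top `topK`
#' (`selection_count`), then by mean test AUC, ties broken
#' lexicographically by pair id, and marks the global top `topK` as
#' selected.
#'
#' Classifiers: `"random_forest"` (default; 100 trees on the single score
#' feature, training AUC from out-of-bag votes) or `"auc_rank"`
#' (threshold-free Mann-Whitney AUC of the raw score, direction-free on
#' training, orientation carried to the test split).
#'
#' @param features a [PairFeatureMatrix-class].
#' @param nBootstraps number of Monte Carlo repeats (default 50).
#' @param trainFrac training fraction of the balanced pool (default 0.6).
#' @param topK pairs selected per bootstrap and globally (default 10;
#'   capped at the number of pairs).
#' @param classifier `"random_forest"` or `"auc_rank"`.
#' @param nTrees Random Forest size (default 100).
#' @param rankBy per-bootstrap ranking criterion, `"train"` (default) or
#'   `"test"` AUC.
#' @param seed integer seed; identical inputs and seed give identical
#'   results.
#' @return a list with `bootstraps` (one data.frame per repeat: pair_id,
#'   train_auc, test_auc, in_top_k, plus train/test sample ids as
#'   attributes) and `ranking` (data.frame: pathway1, pathway2, pair_id,
#'   selection_count, mean_train_auc, mean_test_auc, final_rank, selected).
#' @export
runMccv <- function(features, nBootstraps = 50L, trainFrac = 0.6,
                    topK = 10L, classifier = c("random_forest", "auc_rank"),
                    nTrees = 100L, rankBy = c("train", "test"), seed = 1L) {
  stopifnot(is(features, "PairFeatureMatrix"))
  classifier <- match.arg(classifier)
  rankBy <- match.arg(rankBy)
  scores <- features@scores
  labels <- features@labels[colnames(scores)]
  pairIds <- rownames(scores)
  if (length(pairIds) < 1L) stop("no pathway pairs to evaluate")
  nMin <- min(table(labels))
  if (nMin < 5L) stop("both classes need >= 5 samples")
  if (floor(nMin * trainFrac) < 2L || nMin - floor(nMin * trainFrac) < 2L)
    stop("too few samples for a ", trainFrac, " train split")
  topK <- min(as.integer(topK), length(pairIds))

  set.seed(seed)
  boots <- vector("list", nBootstraps)
  selCount <- setNames(integer(length(pairIds)), pairIds)
  trainSum <- testSum <- setNames(numeric(length(pairIds)), pairIds)
  for (b in seq_len(nBootstraps)) {
    balanced <- unlist(lapply(c("basal", "normal"), function(cl) {
      ids <- names(labels)[labels == cl]
      sample(ids, nMin)
    }), use.names = FALSE)
    trainIds <- unlist(lapply(c("basal", "normal"), function(cl) {
      ids <- balanced[labels[balanced] == cl]
      sample(ids, floor(length(ids) * trainFrac))
    }), use.names = FALSE)
    testIds <- setdiff(balanced, trainIds)
    auc <- t(vapply(pairIds, function(pid)
      .fitPairAuc(scores[pid, trainIds], labels[trainIds],
                  scores[pid, testIds], labels[testIds],
                  classifier, nTrees), numeric(2)))
    crit <- if (rankBy == "train") auc[, "train"] else auc[, "test"]
    ord <- order(-crit, pairIds)
    topIds <- pairIds[ord[seq_len(topK)]]
    selCount[topIds] <- selCount[topIds] + 1L
    trainSum <- trainSum + auc[, "train"]
    testSum <- testSum + auc[, "test"]
    res <- data.frame(pair_id = pairIds, train_auc = unname(auc[, "train"]),
                      test_auc = unname(auc[, "test"]),
                      in_top_k = pairIds %in% topIds,
                      stringsAsFactors = FALSE)
    attr(res, "train_samples") <- trainIds
    attr(res, "test_samples") <- testIds
    boots[[b]] <- res
  }

  ranking <- features@pairs
  ranking$selection_count <- unname(selCount[ranking$pair_id])
  ranking$mean_train_auc <- unname(trainSum[ranking$pair_id] / nBootstraps)
  ranking$mean_test_auc <- unname(testSum[ranking$pair_id] / nBootstraps)
  ord <- order(-ranking$selection_count, -ranking$mean_test_auc,
               ranking$pair_id)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$final_rank <- seq_len(nrow(ranking))
  ranking$selected <- ranking$final_rank <= topK
  rownames(ranking) <- NULL
  list(bootstraps = boots, ranking = ranking)
}
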