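#' Pipeline run configuration
#'
#' Validated bundle of input paths and stage parameters for
#' [runPipeline()]. Precedence when combined with a YAML file through
#' [readRunConfig()]: explicit arguments > file values > defaults.
#'
#' @param mrna,mirna,labels,gmt,targets input file paths (see
#'   [readExpression()], [readGmt()], [readTargets()] for the formats).
#' @param outDir output directory.
#' @param minVariance low-variance filter threshold; `NULL` = bottom-5%
#'   quantile policy.
#' @param logfcThreshold,degAlpha,degMethod,degUseAdjusted Step-1
#'   parameters, see [degTest()].
#' @param enrichAlpha,universePolicy,minSetSize Step-2 parameters, see
#'   [enrichPathways()].
#' @param pairMetric,nBootstraps,trainFrac,topK,classifier,nTrees Step 3-5
#'   parameters, see [pairFeatureMatrix()] and [runMccv()].
#' @param miBins,miPerm,miThresholdP,miAdjust,tumorOnly,alphaMirna Step-6
#'   parameters, see [mirnaGeneLinks()] and [buildNetwork()].
#' @param seed master seed; every stage derives its stream from it.
#' @return a validated list of class `"RunConfig"`.
#' @export
runConfig <- function(mrna, mirna, labels, gmt, targets, outDir = ".",
                      minVariance = NULL, logfcThreshold = 1,
                      degAlpha = 0.01, degMethod = "welch_t",
                      degUseAdjusted = TRUE, enrichAlpha = 0.01,
                      universePolicy = "in_pathways", minSetSize = 3L,
                      pairMetric = "difference", nBootstraps = 50L,
                      trainFrac = 0.6, topK = 10L,
                      classifier = "random_forest", nTrees = 100L,
                      miBins = 3L, miPerm = 999L, miThresholdP = 0.05,
                      miAdjust = FALSE, tumorOnly = TRUE,
                      alphaMirna = 0.05, seed = 1L) {
  cfg <- list(mrna = mrna, mirna = mirna, labels = labels, gmt = gmt,
              targets = targets, outDir = outDir,
              minVariance = minVariance,
              logfcThreshold = as.numeric(logfcThreshold),
              degAlpha = as.numeric(degAlpha), degMethod = degMethod,
              degUseAdjusted = isTRUE(degUseAdjusted),
              enrichAlpha = as.numeric(enrichAlpha),
              universePolicy = universePolicy,
              minSetSize = as.integer(minSetSize),
              pairMetric = pairMetric,
              nBootstraps = as.integer(nBootstraps),
              trainFrac = as.numeric(trainFrac), topK = as.integer(topK),
              classifier = classifier, nTrees = as.integer(nTrees),
              miBins = as.integer(miBins), miPerm = as.integer(miPerm),
              miThresholdP = as.numeric(miThresholdP),
              miAdjust = isTRUE(miAdjust), tumorOnly = isTRUE(tumorOnly),
              alphaMirna = as.numeric(alphaMirna), seed = as.integer(seed))
  for (f in c("mrna", "mirna", "labels", "gmt", "targets"))
    if (!is.character(cfg[[f]]) || length(cfg[[f]]) != 1L)
      stop("'", f, "' must be a single file path")
  if (cfg$trainFrac <= 0 || cfg$trainFrac >= 1)
    stop("'trainFrac' must be in (0, 1)")
  for (f in c("nBootstraps", "topK", "nTrees", "miBins"))
    if (cfg[[f]] < 1L) stop("'", f, "' must be >= 1")
  for (f in c("degAlpha", "enrichAlpha", "miThresholdP", "alphaMirna"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) stop("'", f, "' must be in (0, 1]")
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a RunConfig from a YAML file
#'
#' @param path YAML file of `runConfig()` keys.
#' @param ... explicit overrides, highest precedence.
#' @return a `"RunConfig"` object.
#' @export
readRunConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  unknown <- setdiff(names(vals), names(formals(runConfig)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

.stage <- function(name, expr) {
  message("[", name, "] ", appendLF = FALSE)
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("done (%.1fs)", as.numeric(Sys.time() - t0, "secs")))
  res
}

#' Run the six-step pipeline end to end
#'
#' Steps: (1) differential expression with the low-variance filter, (2)
#' Fisher pathway enrichment, (3) discriminating scores over all pairs of
#' enriched pathways, (4-5) Monte Carlo cross-validated classification and
#' selection of the top pathway pairs, (6) miRNA integration by mutual
#' information and Fisher's exact test with degree centrality.
#'
#' Outputs written to `config$outDir`: `deg.tsv`, `enrichment.tsv`,
#' `pair_ranking.tsv`, `network.json`, `edges.tsv` and `manifest.json`
#' (config echo, stage counts, package version). Files are written with a
#' `.partial` suffix during the run and renamed on success, so an aborted
#' run leaves only `.partial` outputs behind. A stage failure aborts with
#' the stage name and cause.
#'
#' @param config a `"RunConfig"` from [runConfig()] or [readRunConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  cfg <- config
  for (f in c("mrna", "mirna", "labels", "gmt", "targets"))
    if (!file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  if (!dir.exists(cfg$outDir) &&
      !dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", cfg$outDir)
  final <- c(deg = "deg.tsv", enrichment = "enrichment.tsv",
             ranking = "pair_ranking.tsv", network = "network.json",
             edges = "edges.tsv", manifest = "manifest.json")
  final <- setNames(file.path(cfg$outDir, final), names(final))
  part <- setNames(paste0(final, ".partial"), names(final))

  inputs <- .stage("load", list(
    mrna = readExpression(cfg$mrna, cfg$labels),
    mirna = readExpression(cfg$mirna, cfg$labels),
    sets = readGmt(cfg$gmt),
    targets = readTargets(cfg$targets)))

  deg <- .stage("step1_deg", {
    filtered <- lowVarianceFilter(inputs$mrna, cfg$minVariance)
    degTest(filtered, logfcThreshold = cfg$logfcThreshold,
            alpha = cfg$degAlpha, method = cfg$degMethod,
            useAdjusted = cfg$degUseAdjusted)
  })
  writeResultTable(deg, part["deg"])

  enr <- .stage("step2_enrichment",
    enrichPathways(deg, inputs$sets, universePolicy = cfg$universePolicy,
                   alpha = cfg$enrichAlpha, minSetSize = cfg$minSetSize))
  writeResultTable(enr, part["enrichment"])

  enriched <- enr$pathway_id[enr$is_enriched]
  if (length(enriched) < 2L)
    stop("stage 'step3_pairs' failed: ", length(enriched),
         " enriched pathway(s); at least 2 are needed to form pairs")
  mrnaKept <- inputs$mrna[deg$gene_id, ]
  features <- .stage("step3_pairs",
    pairFeatureMatrix(mrnaKept, inputs$sets, pathways = enriched,
                      metric = cfg$pairMetric))

  mccv <- .stage("step4_5_mccv",
    runMccv(features, nBootstraps = cfg$nBootstraps,
            trainFrac = cfg$trainFrac, topK = cfg$topK,
            classifier = cfg$classifier, nTrees = cfg$nTrees,
            seed = cfg$seed + 1L))
  writeResultTable(mccv$ranking, part["ranking"])

  network <- .stage("step6_network", {
    sel <- mccv$ranking[mccv$ranking$selected, ]
    setList <- geneSets(inputs$sets)
    networkGenes <- sort(unique(unlist(
      setList[unique(c(sel$pathway1, sel$pathway2))], use.names = FALSE)))
    networkGenes <- intersect(networkGenes, deg$gene_id)
    links <- mirnaGeneLinks(inputs$mirna, mrnaKept, inputs$targets,
                            networkGenes, miThresholdP = cfg$miThresholdP,
                            nBins = cfg$miBins, nPerm = cfg$miPerm,
                            tumorOnly = cfg$tumorOnly,
                            adjust = cfg$miAdjust, seed = cfg$seed + 2L)
    edges <- targetEdges(inputs$targets)
    universe <- deg$gene_id
    fisherP <- vapply(names(links$supported), function(m)
      mirnaFisher(links$supported[[m]], edges[[m]], networkGenes,
                  universe), numeric(1))
    buildNetwork(mccv$ranking, links, fisherP, inputs$sets, inputs$mirna,
                 alphaMirna = cfg$alphaMirna)
  })
  writeNetwork(network, part["network"], part["edges"])

  manifest <- list(
    package_version = as.character(packageVersion("mirPathNet")),
    config = unclass(cfg),
    seed = cfg$seed,
    counts = list(
      genes_tested = nrow(deg), degs = sum(deg$is_deg),
      pathways_tested = nrow(enr), pathways_enriched = length(enriched),
      pairs_scored = nrow(mccv$ranking),
      pairs_selected = sum(mccv$ranking$selected),
      mirna_links = nrow(networkEdges(network)),
      network_mirnas = nrow(networkMirnas(network))),
    outputs = as.list(setNames(basename(final), names(final))))
  jsonlite::write_json(manifest, part["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)

  for (nm in names(final)) file.rename(part[nm], final[nm])
  invisible(manifest)
}
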