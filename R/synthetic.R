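#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of [generateCohort()]. The defaults
#' describe a desk-scale two-class cohort (40 tumor / 40 normal samples per
#' layer, 300 genes, 50 miRNAs, 12 disjoint pathways of 10-20 genes, 3 of
#' them carrying a planted log2 fold change of 2) with 2 planted regulator
#' miRNAs whose targets inside the planted pathways share a latent signal
#' in the tumor class.
#'
#' @param nTumor number of tumor ("basal") samples, shared between layers.
#' @param nNormalMrna,nNormalMirna number of normal samples in the mRNA and
#'   miRNA layer respectively (layers need not be matched on normals).
#' @param nGenes,nMirnas number of gene / miRNA features.
#' @param nPathways number of gene sets; sets are disjoint.
#' @param pathwaySizeRange integer length-2, min/max genes per pathway
#'   (min >= 3).
#' @param nDePathways number of pathways whose genes carry the planted
#'   tumor shift.
#' @param deLog2fc planted tumor-vs-normal shift, log2 units.
#' @param dispersion standard deviation of expression around the per-gene
#'   baseline, log2 units (> 0).
#' @param nRegulatorMirnas number of planted regulator miRNAs.
#' @param targetsPerRegulator planted targets per regulator, drawn without
#'   replacement from the planted pathways' genes.
#' @param regulationStrength fraction of a target's tumor-class variance
#'   explained by its regulator, in \[0, 1\].
#' @param regulationSign -1 (anti-correlated, canonical miRNA repression)
#'   or +1.
#' @param seed master integer seed; stage sub-generators derive child seeds
#'   by fixed offsets.
#' @return a validated list of class `"SyntheticConfig"`.
#' @examples
#' cfg <- syntheticConfig(nGenes = 100, nMirnas = 20, nPathways = 5)
#' @export
syntheticConfig <- function(nTumor = 40L, nNormalMrna = 40L,
                            nNormalMirna = 40L, nGenes = 300L,
                            nMirnas = 50L, nPathways = 12L,
                            pathwaySizeRange = c(10L, 20L),
                            nDePathways = 3L, deLog2fc = 2,
                            dispersion = 0.25, nRegulatorMirnas = 2L,
                            targetsPerRegulator = 10L,
                            regulationStrength = 0.8,
                            regulationSign = -1L, seed = 1L) {
  cfg <- list(nTumor = as.integer(nTumor),
              nNormalMrna = as.integer(nNormalMrna),
              nNormalMirna = as.integer(nNormalMirna),
              nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
              nPathways = as.integer(nPathways),
              pathwaySizeRange = as.integer(pathwaySizeRange),
              nDePathways = as.integer(nDePathways),
              deLog2fc = as.numeric(deLog2fc),
              dispersion = as.numeric(dispersion),
              nRegulatorMirnas = as.integer(nRegulatorMirnas),
              targetsPerRegulator = as.integer(targetsPerRegulator),
              regulationStrength = as.numeric(regulationStrength),
              regulationSign = as.integer(regulationSign),
              seed = as.integer(seed))
  counts <- c("nTumor", "nNormalMrna", "nNormalMirna", "nGenes", "nMirnas",
              "nPathways")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("invalid SyntheticConfig: '", f, "' must be a positive count")
  for (f in c("nDePathways", "nRegulatorMirnas", "targetsPerRegulator"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("invalid SyntheticConfig: '", f, "' must be a nonnegative count")
  if (length(cfg$pathwaySizeRange) != 2L ||
      cfg$pathwaySizeRange[1L] < 3L ||
      cfg$pathwaySizeRange[1L] > cfg$pathwaySizeRange[2L])
    stop("invalid SyntheticConfig: 'pathwaySizeRange' must be [min, max] ",
         "with min >= 3")
  if (cfg$nDePathways > cfg$nPathways)
    stop("invalid SyntheticConfig: 'nDePathways' exceeds nPathways")
  if (cfg$targetsPerRegulator > cfg$nGenes)
    stop("invalid SyntheticConfig: 'targetsPerRegulator' exceeds nGenes")
  if (cfg$nPathways * cfg$pathwaySizeRange[2L] > cfg$nGenes)
    stop("invalid SyntheticConfig: 'nGenes' too small for nPathways ",
         "disjoint sets of up to ", cfg$pathwaySizeRange[2L], " genes")
  if (cfg$nRegulatorMirnas > cfg$nMirnas)
    stop("invalid SyntheticConfig: 'nRegulatorMirnas' exceeds nMirnas")
  if (cfg$dispersion <= 0)
    stop("invalid SyntheticConfig: 'dispersion' must be > 0")
  if (cfg$regulationStrength < 0 || cfg$regulationStrength > 1)
    stop("invalid SyntheticConfig: 'regulationStrength' must be in [0, 1]")
  if (!cfg$regulationSign %in% c(-1L, 1L))
    stop("invalid SyntheticConfig: 'regulationSign' must be -1 or +1")
  class(cfg) <- "SyntheticConfig"
  cfg
}

# log-normal expression layer: per-entry log2 value = baseline + N(0, sd)
.logNormalLayer <- function(baselines, nSamples, dispersion) {
  n <- length(baselines)
  matrix(baselines, n, nSamples) +
    matrix(rnorm(n * nSamples, sd = dispersion), n, nSamples)
}

#' Generate a synthetic two-layer cohort with known ground truth
#'
#' Draws a gene-expression and a miRNA-expression matrix over a shared set
#' of tumor samples (normal samples are layer-specific), a disjoint pathway
#' collection, and a miRNA target map, with three kinds of planted
#' structure: (i) genes of `nDePathways` pathways are shifted by `deLog2fc`
#' log2 units in tumor samples; (ii) `nRegulatorMirnas` miRNAs receive a
#' fixed +1.5 log2 tumor shift and (iii) each regulator's planted targets
#' (drawn from the planted pathways' genes) share a latent signal with it
#' in the tumor class, so that the squared tumor-class correlation between
#' regulator and target is approximately `regulationStrength`, with sign
#' `regulationSign`. Planted pathways alternate the sign of their shift
#' (up-, then down-regulated in tumors), emulating the mixed-direction
#' dysregulation of real tumor cohorts; the per-pathway signs are recorded
#' in the truth. Expression values are nonnegative continuous
#' normalized-count surrogates: `2^x` for log2-scale draws around per-gene
#' baselines uniform in \[3, 10\].
#'
#' All randomness derives from `config$seed`; stage sub-generators use
#' fixed offsets of it, so identical configurations give identical cohorts.
#'
#' @param config a [syntheticConfig()] object.
#' @return a list of class `"SyntheticCohort"` with elements `mrna` and
#'   `mirna` ([LabeledExpression-class]), `pathways`
#'   ([GeneSetCollection-class]), `targets` ([MirnaTargetMap-class]) and
#'   `truth` (list: `deGenes`, `dePathways`, `dePathwaySigns`,
#'   `deGeneSigns`, `regulatorMirnas`, `regulatorTargets`).
#' @examples
#' co <- generateCohort(syntheticConfig(nGenes = 120, nMirnas = 10,
#'   nPathways = 4, nTumor = 10, nNormalMrna = 10, nNormalMirna = 10,
#'   targetsPerRegulator = 5))
#' dim(exprValues(co$mrna))
#' @export
generateCohort <- function(config = syntheticConfig()) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(syntheticConfig, config)
  cfg <- config

  geneIds <- sprintf("gene%04d", seq_len(cfg$nGenes))
  mirnaIds <- sprintf("mir%03d", seq_len(cfg$nMirnas))
  tumorIds <- sprintf("TUM%03d", seq_len(cfg$nTumor))
  normGIds <- sprintf("NORG%03d", seq_len(cfg$nNormalMrna))
  normMIds <- sprintf("NORM%03d", seq_len(cfg$nNormalMirna))

  # pathways: disjoint gene sets, sizes uniform in the configured range
  set.seed(cfg$seed + 1L)
  sizes <- sample(seq(cfg$pathwaySizeRange[1L], cfg$pathwaySizeRange[2L]),
                  cfg$nPathways, replace = TRUE)
  pool <- sample(geneIds, sum(sizes))
  sets <- split(pool, rep(seq_len(cfg$nPathways), sizes))
  pwIds <- sprintf("PW%02d", seq_len(cfg$nPathways))
  names(sets) <- pwIds
  dePathways <- sort(sample(pwIds, cfg$nDePathways))
  # tumors dysregulate pathways in both directions; alternate the sign of
  # the planted shift so pathway pairs can carry discriminative contrast
  deSigns <- setNames(rep_len(c(1, -1), length(dePathways)), dePathways)
  deGenes <- sort(unique(unlist(sets[dePathways], use.names = FALSE)))
  geneSign <- setNames(rep(0, cfg$nGenes), geneIds)
  for (pw in dePathways) geneSign[sets[[pw]]] <- deSigns[[pw]]

  # mRNA layer
  set.seed(cfg$seed + 2L)
  gBase <- runif(cfg$nGenes, 3, 10)
  mrnaLog <- .logNormalLayer(gBase, cfg$nTumor + cfg$nNormalMrna,
                             cfg$dispersion)
  dimnames(mrnaLog) <- list(geneIds, c(tumorIds, normGIds))
  deIdx <- match(deGenes, geneIds)
  mrnaLog[deIdx, tumorIds] <- mrnaLog[deIdx, tumorIds] +
    geneSign[deGenes] * cfg$deLog2fc

  # miRNA layer; regulators are upregulated in tumors
  set.seed(cfg$seed + 3L)
  mBase <- runif(cfg$nMirnas, 3, 10)
  mirnaLog <- .logNormalLayer(mBase, cfg$nTumor + cfg$nNormalMirna,
                              cfg$dispersion)
  dimnames(mirnaLog) <- list(mirnaIds, c(tumorIds, normMIds))
  regulators <- sort(sample(mirnaIds, cfg$nRegulatorMirnas))
  mirnaLog[regulators, tumorIds] <- mirnaLog[regulators, tumorIds] + 1.5

  # target map: regulators draw disjointly from planted-pathway genes,
  # decoys uniformly from all genes
  set.seed(cfg$seed + 4L)
  regulatorTargets <- list()
  if (cfg$nRegulatorMirnas > 0L && cfg$targetsPerRegulator > 0L) {
    need <- cfg$nRegulatorMirnas * cfg$targetsPerRegulator
    if (need > length(deGenes))
      stop("invalid SyntheticConfig: planted pathways hold ",
           length(deGenes), " genes but ", need,
           " disjoint regulator targets are requested")
    drawn <- sample(deGenes, need)
    regulatorTargets <- split(drawn,
      rep(seq_len(cfg$nRegulatorMirnas), each = cfg$targetsPerRegulator))
    names(regulatorTargets) <- regulators
  }
  edges <- regulatorTargets
  for (m in setdiff(mirnaIds, regulators))
    edges[[m]] <- sample(geneIds, min(cfg$targetsPerRegulator, cfg$nGenes))
  edges <- edges[order(names(edges))]

  # plant tumor-class regulator-target dependence
  set.seed(cfg$seed + 5L)
  if (cfg$regulationStrength > 0 && length(regulatorTargets)) {
    for (m in names(regulatorTargets)) {
      u <- as.numeric(scale(mirnaLog[m, tumorIds]))
      for (g in regulatorTargets[[m]]) {
        eps <- rnorm(cfg$nTumor)
        shift <- geneSign[[g]] * cfg$deLog2fc
        mrnaLog[g, tumorIds] <- gBase[match(g, geneIds)] + shift +
          cfg$dispersion * (cfg$regulationSign *
            sqrt(cfg$regulationStrength) * u +
            sqrt(1 - cfg$regulationStrength) * eps)
      }
    }
  }

  labelsMrna <- setNames(rep(c("basal", "normal"),
                             c(cfg$nTumor, cfg$nNormalMrna)),
                         c(tumorIds, normGIds))
  labelsMirna <- setNames(rep(c("basal", "normal"),
                              c(cfg$nTumor, cfg$nNormalMirna)),
                          c(tumorIds, normMIds))

  cohort <- list(
    mrna = LabeledExpression(2^mrnaLog, labelsMrna),
    mirna = LabeledExpression(2^mirnaLog, labelsMirna),
    pathways = GeneSetCollection(sets, sourceNote = "synthetic"),
    targets = MirnaTargetMap(edges),
    truth = list(deGenes = deGenes, dePathways = dePathways,
                 dePathwaySigns = deSigns,
                 deGeneSigns = geneSign[deGenes],
                 regulatorMirnas = regulators,
                 regulatorTargets = lapply(regulatorTargets, sort)),
    config = cfg)
  class(cohort) <- "SyntheticCohort"
  cohort
}

.formatNum <- function(x) sprintf("%.17g", x)

.writeMatrixTsv <- function(m, path) {
  header <- paste(c("feature_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], .formatNum(m[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
}

#' Write a synthetic cohort to a directory in the pipeline input formats
#'
#' Writes `mrna.tsv`, `mirna.tsv`, `labels.tsv`, `pathways.gmt`,
#' `targets.tsv` and `truth.json`. Numeric values are written with 17
#' significant digits so matrices round-trip bit-identically through
#' [readExpression()].
#'
#' @param cohort a `"SyntheticCohort"` from [generateCohort()].
#' @param outDir output directory, created if absent.
#' @return invisibly, a named character vector of the written file paths.
#' @export
writeCohort <- function(cohort, outDir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  paths <- c(mrna = file.path(outDir, "mrna.tsv"),
             mirna = file.path(outDir, "mirna.tsv"),
             labels = file.path(outDir, "labels.tsv"),
             pathways = file.path(outDir, "pathways.gmt"),
             targets = file.path(outDir, "targets.tsv"),
             truth = file.path(outDir, "truth.json"))
  .writeMatrixTsv(exprValues(cohort$mrna), paths["mrna"])
  .writeMatrixTsv(exprValues(cohort$mirna), paths["mirna"])
  labels <- c(sampleClass(cohort$mrna), sampleClass(cohort$mirna))
  labels <- labels[!duplicated(names(labels))]
  writeLines(c("sample_id\tclass",
               paste(names(labels), labels, sep = "\t")),
             paths["labels"])
  writeGmt(cohort$pathways, paths["pathways"])
  edges <- targetEdges(cohort$targets)
  lines <- c("mirna_id\tgene_id")
  if (length(edges))
    lines <- c(lines, unlist(lapply(names(edges), function(m)
      paste(m, edges[[m]], sep = "\t")), use.names = FALSE))
  writeLines(lines, paths["targets"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(paths)
}
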