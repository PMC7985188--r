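test_that("generator respects the configured shapes and ground truth", {
  cfg <- syntheticConfig(nGenes = 200, nMirnas = 10, nPathways = 10,
                         pathwaySizeRange = c(10, 20), nTumor = 10,
                         nNormalMrna = 12, nNormalMirna = 8,
                         targetsPerRegulator = 5, seed = 3)
  co <- generateCohort(cfg)
  expect_equal(dim(exprValues(co$mrna)), c(200L, 22L))
  expect_equal(dim(exprValues(co$mirna)), c(10L, 18L))
  sets <- geneSets(co$pathways)
  expect_length(sets, 10L)
  expect_true(all(lengths(sets) >= 10 & lengths(sets) <= 20))
  expect_true(all(unlist(sets) %in% rownames(co$mrna)))
  # tumor columns are shared across layers
  tumors <- names(sampleClass(co$mrna))[sampleClass(co$mrna) == "basal"]
  expect_identical(tumors,
    names(sampleClass(co$mirna))[sampleClass(co$mirna) == "basal"])
  # truth invariants
  tr <- co$truth
  expect_setequal(names(tr$regulatorTargets), tr$regulatorMirnas)
  expect_true(all(tr$deGenes %in%
    unlist(sets[tr$dePathways], use.names = FALSE)))
  expect_true(all(unlist(tr$regulatorTargets) %in% tr$deGenes))
})

test_that("identical configurations give identical cohorts", {
  cfg <- syntheticConfig(nGenes = 150, nMirnas = 10, nPathways = 5,
                         nTumor = 10, nNormalMrna = 10, nNormalMirna = 10,
                         targetsPerRegulator = 5, seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(exprValues(a$mrna), exprValues(b$mrna))
  expect_identical(exprValues(a$mirna), exprValues(b$mirna))
  expect_identical(geneSets(a$pathways), geneSets(b$pathways))
  expect_identical(targetEdges(a$targets), targetEdges(b$targets))
  expect_identical(a$truth, b$truth)
})

test_that("planted shift matches its stated moments; null plants nothing", {
  co <- cachedCohort("moments",
    syntheticConfig(seed = 1, nTumor = 40, nNormalMrna = 40,
                    deLog2fc = 2, dispersion = 0.25))
  x <- log2(exprValues(co$mrna) + 1)
  cls <- sampleClass(co$mrna)
  diff <- rowMeans(x[, cls == "basal"]) - rowMeans(x[, cls == "normal"])
  aligned <- diff[co$truth$deGenes] * co$truth$deGeneSigns
  expect_gte(mean(aligned), 1.6)
  expect_lte(mean(aligned), 2.4)

  null <- generateCohort(syntheticConfig(deLog2fc = 0,
                                         regulationStrength = 0, seed = 2))
  xn <- log2(exprValues(null$mrna) + 1)
  clsn <- sampleClass(null$mrna)
  dn <- rowMeans(xn[, clsn == "basal"]) - rowMeans(xn[, clsn == "normal"])
  # sampling error of a mean difference at sd 0.25, n = 40 per class
  expect_lt(max(abs(dn)), 0.3)
  expect_lt(abs(mean(dn)), 0.02)
})

test_that("planted regulator-target correlation matches regulationStrength", {
  co <- defaultCohort()
  cls <- sampleClass(co$mrna)
  tumors <- names(cls)[cls == "basal"]
  xg <- log2(exprValues(co$mrna)[, tumors] + 1)
  xm <- log2(exprValues(co$mirna)[, tumors] + 1)
  r2 <- unlist(lapply(co$truth$regulatorMirnas, function(m)
    vapply(co$truth$regulatorTargets[[m]], function(g)
      cor(xm[m, ], xg[g, ])^2, numeric(1))))
  expect_gt(mean(r2), 0.6)   # target 0.8, finite-sample spread
  expect_lt(mean(r2), 0.95)
  signs <- unlist(lapply(co$truth$regulatorMirnas, function(m)
    vapply(co$truth$regulatorTargets[[m]], function(g)
      sign(cor(xm[m, ], xg[g, ])), numeric(1))))
  expect_true(all(signs == co$config$regulationSign))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(syntheticConfig(nGenes = 0), "nGenes")
  expect_error(syntheticConfig(pathwaySizeRange = c(2, 10)),
               "pathwaySizeRange")
  expect_error(syntheticConfig(nDePathways = 20, nPathways = 12),
               "nDePathways")
  expect_error(syntheticConfig(regulationStrength = 1.5),
               "regulationStrength")
  expect_error(syntheticConfig(dispersion = 0), "dispersion")
  expect_error(syntheticConfig(regulationSign = 0), "regulationSign")
})

test_that("written cohorts round-trip losslessly", {
  co <- generateCohort(syntheticConfig(nGenes = 120, nMirnas = 8,
    nPathways = 4, nTumor = 10, nNormalMrna = 10, nNormalMirna = 10,
    targetsPerRegulator = 5, seed = 5))
  dir <- withr::local_tempdir()
  paths <- writeCohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- readExpression(paths[["mrna"]], paths[["labels"]])
  expect_identical(exprValues(back), exprValues(co$mrna))
  expect_identical(sampleClass(back), sampleClass(co$mrna))
  backMi <- readExpression(paths[["mirna"]], paths[["labels"]])
  expect_identical(exprValues(backMi), exprValues(co$mirna))
  sets <- readGmt(paths[["pathways"]])
  expect_identical(geneSets(sets), geneSets(co$pathways))
  expect_length(readLines(paths[["pathways"]]), 4L)
  tm <- readTargets(paths[["targets"]])
  expect_identical(targetEdges(tm), targetEdges(co$targets))
  # identical config -> byte-identical files
  dir2 <- withr::local_tempdir()
  paths2 <- writeCohort(generateCohort(co$config), dir2)
  for (f in names(paths))
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]),
                     label = f)
})

test_that("an empty target map writes a header-only edge file", {
  co <- generateCohort(syntheticConfig(nGenes = 120, nMirnas = 5,
    nPathways = 4, nTumor = 10, nNormalMrna = 10, nNormalMirna = 10,
    nRegulatorMirnas = 0, targetsPerRegulator = 0, seed = 5))
  co$targets <- MirnaTargetMap()
  dir <- withr::local_tempdir()
  paths <- writeCohort(co, dir)
  expect_identical(readLines(paths[["targets"]]), "mirna_id\tgene_id")
  expect_length(targetEdges(readTargets(paths[["targets"]])), 0L)
})
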