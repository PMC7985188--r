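test_that("mutual information matches hand-computed values", {
  x <- 1:10
  expect_equal(mutualInformation(x, x, nBins = 2, nPerm = 0)$mi, 1)
  expect_equal(mutualInformation(x, rep(3, 10), nPerm = 0)$mi, 0)
  expect_equal(mutualInformation(x, rep(3, 10))$permutation_p, 1)
  # joint counts [[4,1],[1,4]]: MI = 0.8*log2(1.6) + 0.2*log2(0.4)
  y <- c(1, 2, 3, 4, 10, 5, 6, 7, 8, 9)
  expect_equal(mutualInformation(x, y, nBins = 2, nPerm = 0)$mi,
               2 * 0.4 * log2(0.4 / 0.25) + 2 * 0.1 * log2(0.1 / 0.25),
               tolerance = 1e-12)
  expect_error(mutualInformation(1:10, 1:9), "equal length")
  expect_error(mutualInformation(1:5, 1:5), "at least 8")
})

test_that("MI is symmetric, bounded, and equals the histogram oracle", {
  set.seed(21)
  for (i in 1:1000) {
    n <- sample(8:40, 1)
    nBins <- sample(2:4, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    r <- mutualInformation(x, y, nBins = nBins, nPerm = 0)
    expect_equal(r$mi, mutualInformation(y, x, nBins = nBins, nPerm = 0)$mi,
                 tolerance = 1e-12)
    expect_lte(r$mi, log2(nBins) + 1e-12)
    expect_gte(r$mi, -1e-12)
    xb <- ceiling(rank(x, ties.method = "first") * nBins / n)
    yb <- ceiling(rank(y, ties.method = "first") * nBins / n)
    expect_equal(r$mi, bruteForceMi(xb, yb, nBins), tolerance = 1e-12)
  }
})

test_that("degree centrality reproduces the published worked example", {
  dc <- fixtureDegreeCentrality()
  expect_equal(dc[["Hsa-miR-365-2"]], 42L)
  expect_equal(dc[["Hsa-miR-135b"]], 12L)
  # per-slot arithmetic: 15+6 and 6+15 for miR-365, 6+6 for miR-135b
  fx <- loadTable1Fixture()
  expect_identical(vapply(fx, function(r)
    c(length(r$genesP1), length(r$genesP2)), integer(2)),
    matrix(c(6L, 6L, 15L, 6L, 6L, 15L), 2))
  expect_equal(degreeCentrality(list()), 0L)
  # genes are counted once per pathway slot per pair, even when repeated
  expect_equal(degreeCentrality(list(list(c("A", "B"), c("B", "C")),
                                     list("A", character(0)))), 5L)
})

test_that("candidate miRNA-gene links are restricted to the target map", {
  co <- defaultCohort()
  reg <- co$truth$regulatorMirnas[1]
  allGenes <- rownames(co$mrna)
  links <- mirnaGeneLinks(co$mirna, co$mrna,
                          MirnaTargetMap(setNames(list(
                            co$truth$regulatorTargets[[reg]]), reg)),
                          networkGenes = allGenes, nPerm = 99)
  expect_true(all(links$links$mirna_id == reg))
  expect_true(all(links$links$gene_id %in%
                    co$truth$regulatorTargets[[reg]]))
  # a gene outside the map is never linked, whatever its expression
  expect_false("gene0001" %in% links$links$gene_id ||
                 any(vapply(links$supported, function(s)
                   "gene0001" %in% s, logical(1))))
})

test_that("planted regulator links are recovered at high strength", {
  co <- defaultCohort()
  networkGenes <- co$truth$deGenes
  links <- mirnaGeneLinks(co$mirna, co$mrna, co$targets, networkGenes)
  for (reg in co$truth$regulatorMirnas) {
    planted <- co$truth$regulatorTargets[[reg]]
    recovered <- mean(planted %in% links$supported[[reg]])
    expect_gte(recovered, 0.8)
  }
})

test_that("miRNA Fisher test reduces to the 2x2 primitive", {
  universe <- paste0("g", 1:100)
  network <- paste0("g", 1:20)
  targets <- paste0("g", 11:40)
  supported <- paste0("g", 11:18)
  p <- mirnaFisher(supported, targets, network, universe)
  # a=8 supported-in-network, b=20 targets outside, c=10 untargeted network
  expect_equal(p, fisherExactOneSided(8, 20, 10, 62))
  expect_equal(mirnaFisher(character(0), paste0("g", 50:60),
                           paste0("g", 1:10), universe),
               fisherExactOneSided(0, 11, 10, 79))
  expect_error(mirnaFisher("g1", "g1", "g1", character(0)), "universe")
})

test_that("buildNetwork attaches regulators with the top degree centrality", {
  co <- defaultCohort()
  d <- degTest(co$mrna)
  enr <- enrichPathways(d, co$pathways)
  pfm <- pairFeatureMatrix(co$mrna, co$pathways,
                           pathways = enr$pathway_id[enr$is_enriched])
  mccv <- runMccv(pfm, nBootstraps = 5, topK = 10, seed = 2)
  sel <- mccv$ranking[mccv$ranking$selected, ]
  networkGenes <- intersect(unique(unlist(
    geneSets(co$pathways)[unique(c(sel$pathway1, sel$pathway2))])),
    d$gene_id)
  links <- mirnaGeneLinks(co$mirna, co$mrna, co$targets, networkGenes,
                          nPerm = 199)
  edges <- targetEdges(co$targets)
  fisherP <- vapply(names(links$supported), function(m)
    mirnaFisher(links$supported[[m]], edges[[m]], networkGenes,
                d$gene_id), numeric(1))
  net <- buildNetwork(mccv$ranking, links, fisherP, co$pathways, co$mirna)
  mir <- networkMirnas(net)
  expect_setequal(mir$mirna_id[1:2], co$truth$regulatorMirnas)
  expect_true(all(mir$degree_centrality[1:2] >
                    max(0, mir$degree_centrality[-(1:2)])))
  # regulated genes stay inside pathway membership and the miRNA's targets
  for (m in mir$mirna_id) {
    for (pid in names(net@regulatedGenes[[m]])) {
      pair <- net@regulatedGenes[[m]][[pid]]
      pw <- strsplit(pid, "|", fixed = TRUE)[[1]]
      expect_true(all(pair$pathway1 %in% geneSets(co$pathways)[[pw[1]]]))
      expect_true(all(pair$pathway2 %in% geneSets(co$pathways)[[pw[2]]]))
      expect_true(all(c(pair$pathway1, pair$pathway2) %in% edges[[m]]))
    }
  }
  # regulators were planted with a tumor upshift
  expect_true(all(mir$predicted_direction[1:2] == "up"))
})

test_that("a network with no admitted miRNA keeps its pairs", {
  co <- defaultCohort()
  ranking <- data.frame(pathway1 = "PW01", pathway2 = "PW04",
                        pair_id = "PW01|PW04", selection_count = 5L,
                        mean_train_auc = 1, mean_test_auc = 1,
                        final_rank = 1L, selected = TRUE)
  links <- list(links = data.frame(mirna_id = character(),
                                   gene_id = character(),
                                   mi_bits = numeric(), perm_p = numeric(),
                                   retained = logical()),
                supported = list())
  expect_message(net <- buildNetwork(ranking, links,
                                     setNames(numeric(0), character(0)),
                                     co$pathways, co$mirna), "pairs only")
  expect_equal(nrow(networkPairs(net)), 1L)
  expect_equal(nrow(networkMirnas(net)), 0L)
})
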