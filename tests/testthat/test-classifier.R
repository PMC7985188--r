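test_that("pathway activity is the mean of per-gene z-scores", {
  set.seed(1)
  v <- matrix(2^rnorm(40, 6, 1), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  m <- tinyExpression(v, paste0("s", 1:5), paste0("s", 6:10))
  # singleton set: that gene's z-score vector
  x <- log2(v["g1", ] + 1)
  expect_equal(pathwayActivity(m, "g1"),
               (x - mean(x)) / sd(x))
  # mirror-image genes cancel
  x2 <- log2(v["g2", ] + 1)
  v2 <- rbind(a = 2^x2 - 1, b = 2^(2 * mean(x2) - x2) - 1)
  colnames(v2) <- paste0("s", 1:10)
  m2 <- tinyExpression(v2, paste0("s", 1:5), paste0("s", 6:10))
  expect_equal(unname(pathwayActivity(m2, c("a", "b"))), rep(0, 10))
  # constant genes are dropped; all-constant set scores zero
  v3 <- matrix(5, 1, 10, dimnames = list("c1", paste0("s", 1:10)))
  m3 <- tinyExpression(v3, paste0("s", 1:5), paste0("s", 6:10))
  expect_equal(unname(pathwayActivity(m3, "c1")), rep(0, 10))
  expect_error(pathwayActivity(m, "absent", "PWX"), "PWX")
})

test_that("pair scores are antisymmetric differences of activities", {
  co <- defaultCohort()
  sets <- geneSets(co$pathways)
  sAB <- pairScore(co$mrna, sets$PW01, sets$PW02)
  sBA <- pairScore(co$mrna, sets$PW02, sets$PW01)
  expect_equal(sAB, -sBA)
  expect_equal(unname(pairScore(co$mrna, sets$PW01, sets$PW01)),
               rep(0, ncol(co$mrna)))
  expect_equal(sAB, pathwayActivity(co$mrna, sets$PW01) -
                 pathwayActivity(co$mrna, sets$PW02))
})

test_that("AUC equals the Mann-Whitney concordance probability", {
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(rep(1, 6), rep(c(1, 0), 3)), 0.5)
  expect_equal(aucScore(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(aucScore(1:4, rep(1, 4)), "both classes")
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties too
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(aucScore(scores, labels), enumerateAuc(scores, labels))
    expect_gte(aucScore(scores, labels, directionFree = TRUE), 0.5)
  }
})

test_that("a perfectly separating pair dominates the MCCV ranking", {
  set.seed(5)
  n <- 60
  labels <- setNames(rep(c("basal", "normal"), each = n / 2),
                     paste0("s", 1:n))
  signal <- ifelse(labels == "basal", 1, -1) + rnorm(n, sd = 0.05)
  noise <- matrix(rnorm(3 * n), 3, n)
  scores <- rbind(signal, noise)
  rownames(scores) <- c("A|B", "C|D", "C|E", "D|E")
  colnames(scores) <- names(labels)
  pfm <- methods::new("PairFeatureMatrix",
    pairs = data.frame(pathway1 = c("A", "C", "C", "D"),
                       pathway2 = c("B", "D", "E", "E"),
                       pair_id = rownames(scores),
                       stringsAsFactors = FALSE),
    scores = scores, labels = labels)
  res <- runMccv(pfm, nBootstraps = 10, topK = 1, seed = 3)
  rk <- res$ranking
  expect_identical(rk$pair_id[rk$final_rank == 1], "A|B")
  expect_equal(rk$selection_count[rk$pair_id == "A|B"], 10L)
  expect_equal(rk$mean_test_auc[rk$pair_id == "A|B"], 1)
  expect_identical(rk$pair_id[rk$selected], "A|B")
  # balanced splits are disjoint and stratified
  b1 <- res$bootstraps[[1]]
  tr <- attr(b1, "train_samples"); te <- attr(b1, "test_samples")
  expect_length(intersect(tr, te), 0L)
  expect_equal(unname(table(labels[tr])["basal"]),
               unname(table(labels[tr])["normal"]))
})

test_that("MCCV is reproducible and invariant to pair order", {
  co <- defaultCohort()
  pfm <- pairFeatureMatrix(co$mrna, co$pathways,
                           pathways = c("PW01", "PW04", "PW07", "PW02"))
  r1 <- runMccv(pfm, nBootstraps = 5, topK = 3, seed = 42)
  r2 <- runMccv(pfm, nBootstraps = 5, topK = 3, seed = 42)
  expect_identical(r1, r2)
  # same pairs supplied in a different pathway order
  pfm2 <- pairFeatureMatrix(co$mrna, co$pathways,
                            pathways = c("PW07", "PW02", "PW04", "PW01"))
  r3 <- runMccv(pfm2, nBootstraps = 5, topK = 3, seed = 42)
  expect_equal(r1$ranking, r3$ranking)
})

test_that("the auc_rank classifier route agrees on strong signal", {
  co <- defaultCohort()
  pfm <- pairFeatureMatrix(co$mrna, co$pathways,
                           pathways = co$truth$dePathways)
  rf <- runMccv(pfm, nBootstraps = 5, topK = 2, seed = 9)
  ar <- runMccv(pfm, nBootstraps = 5, topK = 2, classifier = "auc_rank",
                seed = 9)
  expect_setequal(rf$ranking$pair_id[rf$ranking$selected],
                  ar$ranking$pair_id[ar$ranking$selected])
})
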