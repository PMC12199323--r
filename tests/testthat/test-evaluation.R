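gridPairs <- function(nCells = 10, nDrugs = 10) {
  p <- expand.grid(cellId = paste0("c", seq_len(nCells)),
                   drugId = paste0("d", seq_len(nDrugs)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p$lnIC50 <- seq_len(nrow(p)) / 10
  p
}

test_that("mix split partitions pairs exhaustively with rounded sizes", {
  p <- gridPairs(2, 5)                       # 10 pairs
  sp <- splitPairs(p, "mix", seed = 1)
  expect_equal(vapply(sp[c("train", "val", "test")], nrow, integer(1)),
               c(train = 8L, val = 1L, test = 1L))
  got <- rbind(sp$train, sp$val, sp$test)
  expect_setequal(paste(got$cellId, got$drugId),
                  paste(p$cellId, p$drugId))
  expect_equal(sp$nDiscarded, 0L)
})

test_that("entity splits never share cells or drugs across partitions", {
  p <- gridPairs()
  for (seed in c(1, 7, 23)) {
    spc <- splitPairs(p, "cell", seed = seed)
    expect_length(Reduce(intersect, lapply(spc[1:3], `[[`, "cellId")), 0L)
    expect_equal(nrow(spc$train) + nrow(spc$val) + nrow(spc$test), nrow(p))
    spd <- splitPairs(p, "drug", seed = seed)
    expect_length(Reduce(intersect, lapply(spd[1:3], `[[`, "drugId")), 0L)
  }
})

test_that("both split keeps only doubly-assigned pairs and counts discards", {
  p <- gridPairs()
  sp <- splitPairs(p, "both", seed = 3)
  kept <- nrow(sp$train) + nrow(sp$val) + nrow(sp$test)
  expect_equal(kept + sp$nDiscarded, nrow(p))
  expect_gt(sp$nDiscarded, 0)
  # test cells and drugs are unseen in training
  expect_length(intersect(sp$test$cellId, sp$train$cellId), 0L)
  expect_length(intersect(sp$test$drugId, sp$train$drugId), 0L)
  # 8:1:1 over a 10x10 grid: one test cell x one test drug
  expect_equal(nrow(sp$test), 1L)
})

test_that("degenerate splits error instead of returning empty partitions", {
  p <- gridPairs(2, 2)
  expect_error(splitPairs(p[1:3, ], "mix", fractions = c(0.9, 0.05, 0.05)),
               "empty|few")
  expect_error(splitPairs(p, "mix", fractions = c(0.5, 0.5, 0.5)), "summing")
})

test_that("regression metrics match closed forms", {
  obs <- c(1, 2, 4)
  expect_equal(regressionMetrics(obs, obs), list(pcc = 1, rmse = 0))
  expect_equal(regressionMetrics(-obs, obs)$pcc, -1)
  m <- regressionMetrics(obs + 1, obs)
  expect_equal(m$rmse, 1)
  expect_equal(m$pcc, 1)
  expect_true(is.na(regressionMetrics(obs, c(2, 2, 2))$pcc))
  # hand-computed 3-point case
  pred <- c(0, 1, 3)
  expect_equal(regressionMetrics(pred, obs)$rmse,
               sqrt(mean(c(1, 1, 1)^2)), tolerance = 1e-12)
  expect_equal(regressionMetrics(pred, obs)$pcc,
               cov(pred, obs) / (sd(pred) * sd(obs)), tolerance = 1e-12)
})

test_that("quartile classification follows the printed toy example", {
  obs <- 0:7
  # linear-interpolation 25th percentile of 0..7
  qc <- quartileClassification(obs, obs)
  expect_equal(qc$tau, 1.75)
  expect_equal(sum(qc$labelsObs), 2L)        # exactly 2 observed sensitives
  expect_equal(qc$f1, 1)
  expect_equal(qc$auroc, 1)
  rev <- quartileClassification(rev(obs), obs)
  expect_equal(rev$auroc, 0)
  expect_error(quartileClassification(obs, rep(1, 8)), "identical")
})

test_that("AUROC agrees with the rank-statistic oracle", {
  set.seed(31)
  for (i in 1:10) {
    score <- rnorm(40)
    label <- rbinom(40, 1, 0.4) == 1
    if (length(unique(label)) < 2) next
    expect_equal(driverSigDR:::aurocFromScores(score, label),
                 aurocOracle(score, label), tolerance = 1e-12)
  }
})

test_that("per-entity metrics skip small or constant entities", {
  pairs <- data.frame(
    cellId = c(rep("c1", 5), rep("c2", 2), rep("c3", 4)),
    drugId = paste0("d", c(1:5, 1:2, 1:4)),
    lnIC50 = c(1, 2, 3, 4, 5, 1, 2, 2, 2, 2, 2))
  pred <- c(1, 2, 3, 4, 5, 9, 9, 1, 2, 3, 4)
  res <- perEntityMetrics(pairs, pred, by = "cell")
  expect_equal(res$nSkipped, 2L)             # c2 too small, c3 constant
  expect_equal(res$reports$pcc[res$reports$entity == "c1"], 1)

  two <- data.frame(cellId = rep(c("a", "b"), each = 3),
                    drugId = paste0("d", c(1:3, 1:3)),
                    lnIC50 = c(1, 2, 3, 1, 2, 3))
  predTwo <- c(1, 2, 2.5, 3, 1, 2)
  r2 <- perEntityMetrics(two, predTwo, by = "cell")
  ms <- r2$summary
  expect_equal(ms$mean[ms$metric == "pcc"], mean(r2$reports$pcc))
  expect_equal(ms$sd[ms$metric == "pcc"], sd(r2$reports$pcc))
})

test_that("Monte Carlo cross-validation is seeded and reports per iteration", {
  co <- smallTestCohort()
  sets <- co@geneSets[sprintf("pathway_%02d", 1:3)]
  act <- activityMatrix(co@expression, sets)
  features <- list(activity = act, mutations = co@mutations,
                   fingerprints = co@fingerprints)
  builder <- function(seed)
    buildModel(rownames(act),
               mutSpec = list(inputDim = nrow(co@mutations), h1 = 10,
                              h2 = 5, bottleneck = 3),
               drugSpec = list(inputDim = 128, h1 = 24, h2 = 10,
                               bottleneck = 5), seed = seed)
  cfg <- list(lr = 2e-3, batchSize = 128L, maxEpochs = 8L, patience = 8L)
  res <- monteCarloCV(co@pairs, features, builder, cfg, nIter = 2, seed = 77)
  expect_equal(nrow(res$reports), 2L)
  expect_true(all(is.finite(res$reports$pcc)))
  res2 <- monteCarloCV(co@pairs, features, builder, cfg, nIter = 2, seed = 77)
  expect_identical(res$reports, res2$reports)
})
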