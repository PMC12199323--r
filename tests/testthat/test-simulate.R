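test_that("simulated networks are connected, symmetric and near target degree", {
  for (s in 1:10) {
    res <- simulateNetwork(500, avgDegree = 8, nModules = 20, seed = s)
    A <- adjacencyMatrix(res$network)
    expect_true(Matrix::isSymmetric(A))
    expect_true(all(Matrix::diag(A) == 0))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1L)
    realized <- mean(Matrix::colSums(A))
    expect_lt(abs(realized - 8) / 8, 0.2)
  }
  # degenerate single-module case still works
  one <- simulateNetwork(50, avgDegree = 4, nModules = 1, seed = 1)
  expect_equal(igraph::components(
    igraph::graph_from_adjacency_matrix(adjacencyMatrix(one$network),
                                        mode = "undirected"))$no, 1L)
  expect_error(simulateNetwork(10, avgDegree = 20, nModules = 2), "degree")
})

test_that("cohort generation is fully determined by its seed", {
  sp <- cohortSpec(nGenes = 120, nCells = 20, nDrugs = 6, nPathways = 6,
                   nDecoys = 3, nDriverGenes = 10, nDriverModules = 2,
                   nBits = 64, seed = 5)
  a <- simulateCohort(sp)
  b <- simulateCohort(sp)
  expect_identical(a@expression, b@expression)
  expect_identical(a@mutations, b@mutations)
  expect_identical(a@fingerprints, b@fingerprints)
  expect_identical(a@pairs, b@pairs)
  expect_identical(a@driverGenes, b@driverGenes)
  c2 <- simulateCohort(cohortSpec(nGenes = 120, nCells = 20, nDrugs = 6,
                                  nPathways = 6, nDecoys = 3,
                                  nDriverGenes = 10, nDriverModules = 2,
                                  nBits = 64, seed = 6))
  expect_false(identical(a@pairs$lnIC50, c2@pairs$lnIC50))
})

test_that("noise-free cohorts reproduce the generative formula exactly", {
  sp <- cohortSpec(nGenes = 120, nCells = 20, nDrugs = 6, nPathways = 6,
                   nDecoys = 3, nDriverGenes = 10, nDriverModules = 2,
                   nBits = 64, noiseSd = 0, seed = 3)
  co <- simulateCohort(sp)
  gt <- co@groundTruth
  expect_equal(co@pairs$lnIC50, gt$noiselessResponse, tolerance = 1e-12)
  # recompute from the stored latents
  rebuilt <- sp$activityEffect * gt$activityComponent[co@pairs$cellId] +
    sp$mutationEffect * gt$mutationLatent[co@pairs$cellId] +
    sp$drugEffect * gt$drugLatent[co@pairs$drugId] +
    sp$interactionEffect * gt$activityComponent[co@pairs$cellId] *
      gt$drugLatent[co@pairs$drugId]
  expect_equal(co@pairs$lnIC50, unname(rebuilt), tolerance = 1e-12)
})

test_that("true latents explain the designed share of response variance", {
  co <- simulateCohort(cohortSpec())
  gt <- co@groundTruth
  df <- data.frame(
    y = co@pairs$lnIC50,
    act = gt$activityComponent[co@pairs$cellId],
    mut = gt$mutationLatent[co@pairs$cellId],
    drg = gt$drugLatent[co@pairs$drugId])
  df$inter <- df$act * df$drg
  set.seed(1)
  hold <- sample(nrow(df), 2000)
  fit <- lm(y ~ act + mut + drg + inter, data = df[-hold, ])
  pred <- predict(fit, df[hold, ])
  r2 <- 1 - mean((df$y[hold] - pred)^2) / var(df$y[hold])
  expect_gte(r2, 0.75)
  expect_lte(r2, 0.85)
})

test_that("ssGSEA activities track the planted latent activities", {
  co <- simulateCohort(cohortSpec(noiseSd = 0))
  driverPW <- sprintf("pathway_%02d", co@groundTruth$driverModules)
  act <- activityMatrix(co@expression, co@geneSets[driverPW])
  for (pw in driverPW) {
    r <- cor(act[pw, ], co@groundTruth$latentActivity[pw, ])
    expect_gt(abs(r), 0.7)
    expect_gt(r, 0)         # positive loadings give positively aligned scores
  }
})

test_that("fixtures round-trip through plain-text files", {
  co <- simulateCohort(cohortSpec(nGenes = 100, nCells = 12, nDrugs = 5,
                                  nPathways = 5, nDecoys = 2,
                                  nDriverGenes = 8, nDriverModules = 2,
                                  nBits = 32, seed = 8))
  dir <- withr::local_tempdir()
  manifest <- writeFixture(co, dir)
  expect_length(readLines(file.path(dir, "genesets.gmt")),
                length(co@geneSets))
  back <- readFixture(dir)
  expect_identical(back@expression, co@expression)
  expect_identical(back@mutations, co@mutations)
  expect_identical(unname(back@fingerprints), unname(co@fingerprints))
  expect_identical(colnames(back@fingerprints), colnames(co@fingerprints))
  expect_equal(back@pairs, co@pairs)
  expect_identical(back@geneSets, co@geneSets)
  expect_identical(back@driverGenes, co@driverGenes)
  expect_identical(as.matrix(adjacencyMatrix(back@network)),
                   as.matrix(adjacencyMatrix(co@network)))
  expect_equal(back@groundTruth$noiselessResponse,
               co@groundTruth$noiselessResponse, tolerance = 1e-12)

  # checksums change iff file content changes
  before <- manifest$checksums[["pairs.tsv"]]
  expect_identical(unname(tools::md5sum(file.path(dir, "pairs.tsv"))),
                   before)
  pr <- co@pairs; pr$lnIC50[1] <- pr$lnIC50[1] + 1
  co2 <- co; co2@pairs <- pr
  m2 <- writeFixture(co2, dir)
  expect_false(identical(m2$checksums[["pairs.tsv"]], before))
  expect_identical(m2$checksums[["drivers.txt"]],
                   manifest$checksums[["drivers.txt"]])
})
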