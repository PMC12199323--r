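test_that("edges require support from enough distinct sources", {
  rec <- data.frame(
    geneA = c("A", "B", "B", "C", "C", "D", "D", "D", "E", "F"),
    geneB = c("B", "C", "C", "D", "D", "E", "E", "E", "F", "G"),
    source = c("s1", "s1", "s2", "s1", "s2", "s1", "s2", "s3", "s1", "s1"))
  # distinct-source counts per pair: AB 1, BC 2, CD 2, DE 3, EF 1, FG 1
  net <- filterEdges(rec, minSources = 2)
  expect_equal(networkEdges(net), 3L)
  expect_false(any(c("A", "F", "G") %in% networkNodes(net)))

  one <- data.frame(geneA = "X", geneB = "Y", source = "only")
  expect_error(filterEdges(one, minSources = 2), "at least 2")
  both <- rbind(one, data.frame(geneA = "Y", geneB = "X", source = "other"))
  expect_equal(networkEdges(filterEdges(both, minSources = 2)), 1L)
})

test_that("edge filtering rejects malformed and degenerate input", {
  expect_error(filterEdges(data.frame()), "non-empty")
  bad <- data.frame(geneA = c("A", ""), geneB = c("B", "C"),
                    source = c("s", "s"))
  expect_error(filterEdges(bad), "row\\(s\\): 2")
  # self-pairs never create edges
  selfy <- data.frame(geneA = c("A", "A"), geneB = c("A", "B"),
                      source = c("s1", "s2"))
  net <- filterEdges(selfy, minSources = 1)
  expect_equal(networkEdges(net), 1L)
})

test_that("largest component extraction keeps order and breaks ties by node id", {
  # connected graph unchanged
  net <- pathNetwork(6)
  expect_identical(networkNodes(largestComponent(net)), networkNodes(net))

  # components of sizes 5 and 3
  rec <- data.frame(
    geneA = c("a1", "a2", "a3", "a4", "b1", "b2"),
    geneB = c("a2", "a3", "a4", "a5", "b2", "b3"),
    source = "s")
  net <- filterEdges(rec, minSources = 1)
  lc <- largestComponent(net)
  expect_setequal(networkNodes(lc), paste0("a", 1:5))

  # two components of size 4: the one holding the smallest id wins
  rec <- data.frame(
    geneA = c("m1", "m2", "m3", "a1", "a2", "a3"),
    geneB = c("m2", "m3", "m4", "a2", "a3", "a4"),
    source = "s")
  lc <- largestComponent(filterEdges(rec, minSources = 1))
  expect_setequal(networkNodes(lc), paste0("a", 1:4))
})

test_that("column normalization yields a stochastic matrix", {
  net <- pathNetwork(3)                      # A-B-C
  tm <- normalizeColumns(net)
  expect_equal(as.numeric(tm[, "B"]), c(0.5, 0, 0.5))
  expect_equal(as.numeric(tm[, "A"]), c(0, 1, 0))

  rnet <- randomConnectedNetwork(20, seed = 3)
  expect_lt(max(abs(Matrix::colSums(normalizeColumns(rnet)) - 1)), 1e-12)

  # isolated node signals missing component extraction
  A <- Matrix::Matrix(0, 2, 2, sparse = TRUE,
                      dimnames = list(c("x", "y"), c("x", "y")))
  lone <- methods::new("PPINetwork", nodes = c("x", "y"), adjacency = A)
  expect_error(normalizeColumns(lone), "zero-degree")
})

test_that("seed vectors spread unit mass over mapped seeds", {
  net <- pathNetwork(4)
  c0 <- makeSeedVector(net, c("A", "C", "Z"))
  expect_equal(unname(c0[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(c0), 1)
  expect_equal(attr(c0, "nUnmapped"), 1L)
  expect_error(makeSeedVector(net, c("Q", "Z")), "map into")

  net10 <- randomConnectedNetwork(10, seed = 5)
  c0 <- makeSeedVector(net10, networkNodes(net10))
  expect_true(all(c0 == 0.1))
})

test_that("propagation matches the closed-form fixed point", {
  # 2-node single edge, seed on node 1, beta = 0.9: c = (10/11, 1/11)
  net <- pathNetwork(2)
  tm <- normalizeColumns(net)
  c0 <- makeSeedVector(net, "A")
  res <- propagate(tm, c0, beta = 0.9)
  expect_true(res$converged)
  expect_equal(unname(res$scores), c(10 / 11, 1 / 11), tolerance = 1e-9)

  # random graphs against the direct linear solve
  for (s in 1:5) {
    n <- sample(5:30, 1)
    net <- randomConnectedNetwork(n, seed = s)
    tm <- normalizeColumns(net)
    c0 <- makeSeedVector(net, sample(networkNodes(net), 3))
    res <- propagate(tm, c0, beta = 0.9)
    expect_lt(max(abs(res$scores - rwrClosedForm(tm, c0, 0.9))), 1e-8)
    expect_equal(sum(res$scores), 1, tolerance = 1e-9)
  }
})

test_that("propagation limits and flags behave as specified", {
  net <- randomConnectedNetwork(8, seed = 2)
  tm <- normalizeColumns(net)
  c0 <- makeSeedVector(net, networkNodes(net)[1:2])
  # beta = 1: restart dominates, c = c0 after one iteration
  res <- propagate(tm, c0, beta = 1)
  expect_equal(unname(res$scores), as.numeric(c0))
  expect_equal(res$iterations, 1L)
  # exhausted iteration budget flags non-convergence without erroring
  res <- propagate(tm, c0, beta = 0.1, tol = 1e-16, maxIter = 3L)
  expect_false(res$converged)
  expect_equal(res$iterations, 3L)
  # non-stochastic matrix is rejected
  expect_error(propagate(adjacencyMatrix(net), c0), "column-stochastic")
  # determinism: bitwise-identical reruns
  expect_identical(propagate(tm, c0), propagate(tm, c0))
})

test_that("propagation decays with distance from the seed on a path", {
  net <- pathNetwork(7)
  tm <- normalizeColumns(net)
  c0 <- makeSeedVector(net, "A")
  sc <- propagate(tm, c0)$scores
  expect_true(all(diff(sc) < 0))     # monotone in distance from A
})

test_that("network edge lists round-trip through TSV", {
  net <- randomConnectedNetwork(12, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePPIEdges(net, f)
  back <- filterEdges(cbind(readPPIEdges(f), source = "x"), minSources = 1)
  expect_equal(networkEdges(back), networkEdges(net))
  expect_setequal(networkNodes(back), networkNodes(net))
})
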