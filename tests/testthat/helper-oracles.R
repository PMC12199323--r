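# Independent oracles and small generators shared across tests.
# These deliberately re-derive quantities by a different route than the
# package implementation (closed forms, scalar loops, prefix sums).

# closed-form RWR fixed point: beta (I - (1-beta) T)^-1 c0
rwrClosedForm <- function(transition, c0, beta) {
  n <- length(c0)
  as.numeric(solve(diag(n) - (1 - beta) * as.matrix(transition),
                   beta * as.numeric(c0)))
}

# random connected undirected graph as a PPINetwork
randomConnectedNetwork <- function(n, pEdge = 0.15, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, pEdge)
    A <- A + t(A)
    # chain the nodes so the graph is always connected
    for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
    diag(A) <- 0
    break
  }
  nodes <- sprintf("n%02d", seq_len(n))
  methods::new("PPINetwork", nodes = nodes,
               adjacency = Matrix::Matrix(A, sparse = TRUE,
                                          dimnames = list(nodes, nodes)))
}

pathNetwork <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  nodes <- LETTERS[seq_len(n)]
  methods::new("PPINetwork", nodes = nodes,
               adjacency = Matrix::Matrix(A, sparse = TRUE,
                                          dimnames = list(nodes, nodes)))
}

# literal running-sum ES oracle (position loop, no vectorization)
esOracle <- function(ranked, geneSet, exponent) {
  genes <- names(ranked)
  N <- length(genes)
  hit <- genes %in% geneSet
  m <- sum(hit)
  nr <- sum(abs(ranked[hit])^exponent)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + abs(ranked[i])^exponent / nr
           else cur - 1 / (N - m)
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# literal ssGSEA oracle: explicit position-by-position running sums
ssgseaOracle <- function(expr, geneSet, alpha) {
  N <- length(expr)
  ord <- order(-as.numeric(expr))
  genes <- names(expr)[ord]
  hit <- genes %in% geneSet
  rankValue <- (N:1)^alpha
  num <- 0; den <- sum(rankValue[hit])
  miss <- 0; total <- 0
  for (i in seq_len(N)) {
    if (hit[i]) num <- num + rankValue[i] else miss <- miss + 1
    total <- total + num / den - miss / (N - sum(hit))
  }
  total
}

# scalar-loop unified loss oracle
unifiedLossOracle <- function(s, sPred, Rc, pC, Rd, pD, lC, lD) {
  mse <- 0
  for (i in seq_along(s)) mse <- mse + (s[i] - sPred[i])^2
  mse <- mse / length(s)
  bce <- function(Tg, P) {
    acc <- 0
    for (i in seq_along(Tg))
      acc <- acc - (Tg[i] * log(P[i]) + (1 - Tg[i]) * log(1 - P[i]))
    acc / length(Tg)
  }
  mse + lC * bce(as.numeric(Rc), as.numeric(pC)) +
    lD * bce(as.numeric(Rd), as.numeric(pD))
}

# Mann-Whitney rank AUROC oracle (higher score = positive)
aurocOracle <- function(score, label) {
  r <- rank(score)
  nPos <- sum(label); nNeg <- sum(!label)
  (sum(r[label]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# a small cohort reused by several test files (memoized per session)
.testCohortEnv <- new.env()
smallTestCohort <- function() {
  if (is.null(.testCohortEnv$co))
    .testCohortEnv$co <- simulateCohort(cohortSpec(
      nGenes = 200, nCells = 60, nDrugs = 12, nPathways = 10, nDecoys = 6,
      nDriverGenes = 20, nDriverModules = 3, nBits = 128, seed = 42))
  .testCohortEnv$co
}

# tiny affine "predictor" wrapped in a DeepSensModel, for attribution tests
affineModel <- function(w, b = 0) {
  model <- buildModel(signaturePathways = paste0("p", seq_along(w)),
                      mutSpec = list(inputDim = 4, h1 = 3, h2 = 2, bottleneck = 1),
                      drugSpec = list(inputDim = 4, h1 = 3, h2 = 2, bottleneck = 1),
                      seed = 1)
  net <- driverSigDR:::mlpBuild(c(length(w), 1L), "linear", FALSE, seed = 1)
  net$layers[[1]]$W <- matrix(w, ncol = 1)
  net$layers[[1]]$b <- b
  model@fnn <- net
  model
}
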