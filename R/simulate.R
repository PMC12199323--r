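#' Default synthetic-cohort specification
#'
#' The default cohort: 500 genes in a modular interaction network, 200
#' cells, 50 drugs, 20 planted pathway modules (plus 20 decoy sets), 40
#' driver genes concentrated in 5 response-relevant modules, Bernoulli(0.1)
#' 1024-bit fingerprints, and LN IC50 built from pathway-activity, mutation
#' and drug latents with equal weights, a small cell-drug interaction, and
#' Gaussian noise at half the signal's standard deviation.
#'
#' @param ... named overrides of any field.
#' @return a complete specification list.
#' @export
cohortSpec <- function(...) {
  spec <- list(
    nGenes = 500L, nCells = 200L, nDrugs = 50L,
    nPathways = 20L, nDecoys = 20L, pathwaySizeRange = c(15L, 35L),
    nDriverGenes = 40L, nDriverModules = 5L,
    networkAvgDegree = 8, withinModuleFraction = 0.8,
    nBits = 1024L, fingerprintDensity = 0.1,
    mutationRateRange = c(0.05, 0.4),
    loadingRange = c(0.5, 1.5), exprNoiseSd = 1,
    activityEffect = 1, mutationEffect = 1, drugEffect = 1,
    interactionEffect = 0.3,
    noiseSd = 0.5,   # as a fraction of the realized signal sd
    seed = 1L)
  ov <- list(...)
  stopIfNot(all(names(ov) %in% names(spec)),
            paste("unknown spec field(s):",
                  paste(setdiff(names(ov), names(spec)), collapse = ", ")))
  utils::modifyList(spec, ov)
}

#' Simulate a modular gene interaction network
#'
#' Stochastic-block-style graph: genes are split evenly into modules and a
#' target edge budget (nGenes * avgDegree / 2) is spent mostly within
#' modules, the rest between. A spanning chain over connected components is
#' added afterwards, so the result is always connected, symmetric and
#' self-loop-free.
#'
#' @param nGenes,nModules counts (nGenes >= nModules >= 1).
#' @param avgDegree requested average degree (< nGenes - 1).
#' @param withinFraction fraction of edges placed within modules; default 0.8.
#' @param seed integer seed.
#' @param geneNames optional node names; default gene0001...
#' @return list: `network` ([PPINetwork-class]), `modules` (named integer
#'   vector gene -> module).
#' @export
simulateNetwork <- function(nGenes, avgDegree, nModules, seed = 1L,
                            withinFraction = 0.8, geneNames = NULL) {
  stopIfNot(nGenes >= nModules && nModules >= 1, "need nGenes >= nModules >= 1")
  stopIfNot(avgDegree >= 1 && avgDegree < nGenes - 1, "infeasible average degree")
  genes <- geneNames %||% sprintf("gene%04d", seq_len(nGenes))
  modules <- stats::setNames(rep(seq_len(nModules), length.out = nGenes)[
    order(rep(seq_len(nModules), length.out = nGenes))], genes)
  targetEdges <- round(nGenes * avgDegree / 2)
  withSeed(substreamSeed(seed, "network"), {
    pairs <- matrix(integer(), 0, 2)
    nWithin <- round(withinFraction * targetEdges)
    perModule <- largestRemainder(nWithin, rep(1 / nModules, nModules))
    for (m in seq_len(nModules)) {
      idx <- which(modules == m)
      nPoss <- length(idx) * (length(idx) - 1) / 2
      k <- min(perModule[m], nPoss)
      if (k > 0) {
        # sample k distinct unordered pairs
        ut <- which(upper.tri(diag(length(idx))), arr.ind = TRUE)
        sel <- ut[sample.int(nrow(ut), k), , drop = FALSE]
        pairs <- rbind(pairs, cbind(idx[sel[, 1]], idx[sel[, 2]]))
      }
    }
    nBetween <- targetEdges - nrow(pairs)
    if (nBetween > 0) {
      got <- matrix(integer(), 0, 2)
      tries <- 0
      while (nrow(got) < nBetween && tries < 20) {
        tries <- tries + 1
        i <- sample.int(nGenes, 2 * nBetween, replace = TRUE)
        j <- sample.int(nGenes, 2 * nBetween, replace = TRUE)
        keep <- modules[i] != modules[j]
        cand <- cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep]))
        got <- unique(rbind(got, cand))
      }
      pairs <- rbind(pairs, got[seq_len(min(nBetween, nrow(got))), , drop = FALSE])
    }
    pairs <- unique(pairs)
    A <- Matrix::sparseMatrix(i = c(pairs[, 1], pairs[, 2]),
                              j = c(pairs[, 2], pairs[, 1]), x = 1,
                              dims = c(nGenes, nGenes),
                              dimnames = list(genes, genes))
    A@x[] <- 1
    # connect components along a chain of their first members
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no > 1) {
      reps <- vapply(seq_len(comp$no),
                     function(k) which(comp$membership == k)[1], integer(1))
      for (k in seq_len(length(reps) - 1))
        A[reps[k], reps[k + 1]] <- A[reps[k + 1], reps[k]] <- 1
    }
    list(network = methods::new("PPINetwork", nodes = genes, adjacency = A),
         modules = modules)
  })
}

#' Simulate a complete synthetic drug-sensitivity cohort
#'
#' Generates, from one master seed via named substreams: a modular gene
#' network whose modules double as planted pathways (plus random decoy
#' sets); driver genes concentrated in a subset of response-relevant
#' modules; per-cell latent pathway activities (standard normal) expressed
#' as noisy loadings in the expression matrix; Bernoulli driver mutations
#' whose weighted sum forms a per-cell mutation latent; Bernoulli
#' fingerprint bits whose weighted sum forms a per-drug latent; and LN IC50
#' for every cell-drug pair as
#' activityEffect * a(c) + mutationEffect * m(c) + drugEffect * d(drug) +
#' interactionEffect * a(c) * d(drug) + Normal(0, noiseSd * sd(signal)),
#' where a(c) averages the latent activities of the driver modules and all
#' latents are standardized. The ground truth stores every latent and
#' weight, so the noiseless response is exactly recomputable.
#'
#' @param spec a specification list from [cohortSpec()].
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  sp <- spec
  net <- simulateNetwork(sp$nGenes, sp$networkAvgDegree, sp$nPathways,
                         seed = substreamSeed(sp$seed, "net"),
                         withinFraction = sp$withinModuleFraction)
  genes <- networkNodes(net$network)
  modules <- net$modules
  cells <- sprintf("cell%03d", seq_len(sp$nCells))
  drugs <- sprintf("drug%02d", seq_len(sp$nDrugs))
  pwNames <- sprintf("pathway_%02d", seq_len(sp$nPathways))
  geneSets <- stats::setNames(
    lapply(seq_len(sp$nPathways), function(m) names(modules)[modules == m]),
    pwNames)
  # decoy sets: random gene draws, no planted structure
  decoys <- withSeed(substreamSeed(sp$seed, "decoys"), {
    stats::setNames(lapply(seq_len(sp$nDecoys), function(k) {
      sz <- sample(sp$pathwaySizeRange[1]:sp$pathwaySizeRange[2], 1)
      sample(genes, sz)
    }), sprintf("decoy_%02d", seq_len(sp$nDecoys)))
  })
  geneSets <- c(geneSets, decoys)
  # drivers concentrated in the response-relevant modules
  driverModules <- seq_len(sp$nDriverModules)
  driverGenes <- withSeed(substreamSeed(sp$seed, "drivers"), {
    perMod <- largestRemainder(sp$nDriverGenes,
                               rep(1 / sp$nDriverModules, sp$nDriverModules))
    unlist(lapply(seq_along(driverModules), function(k) {
      pool <- names(modules)[modules == driverModules[k]]
      sample(pool, min(perMod[k], length(pool)))
    }))
  })
  # latent pathway activities and expression
  L <- withSeed(substreamSeed(sp$seed, "activity"),
                matrix(stats::rnorm(sp$nPathways * sp$nCells), sp$nPathways,
                       dimnames = list(pwNames, cells)))
  expression <- withSeed(substreamSeed(sp$seed, "expression"), {
    loading <- stats::runif(sp$nGenes, sp$loadingRange[1], sp$loadingRange[2])
    E <- loading * L[modules[genes], , drop = FALSE] +
      matrix(stats::rnorm(sp$nGenes * sp$nCells, sd = sp$exprNoiseSd),
             sp$nGenes)
    dimnames(E) <- list(genes, cells)
    E
  })
  # driver mutations and the per-cell mutation latent
  mut <- withSeed(substreamSeed(sp$seed, "mutation"), {
    rates <- stats::runif(length(driverGenes), sp$mutationRateRange[1],
                          sp$mutationRateRange[2])
    M <- matrix(stats::rbinom(length(driverGenes) * sp$nCells, 1,
                              rep(rates, sp$nCells)),
                length(driverGenes), dimnames = list(driverGenes, cells))
    storage.mode(M) <- "double"
    v <- stats::rnorm(length(driverGenes))
    lat <- as.numeric(crossprod(M, v))
    list(M = M, v = v, latent = standardize(lat, cells))
  })
  # drug fingerprints and the per-drug latent
  fp <- withSeed(substreamSeed(sp$seed, "drugs"), {
    F <- matrix(stats::rbinom(sp$nBits * sp$nDrugs, 1, sp$fingerprintDensity),
                sp$nBits, dimnames = list(NULL, drugs))
    storage.mode(F) <- "double"
    u <- stats::rnorm(sp$nBits)
    lat <- as.numeric(crossprod(F, u))
    list(F = F, u = u, latent = standardize(lat, drugs))
  })
  # response over the complete cell x drug grid
  wPW <- rep(0, sp$nPathways)
  wPW[driverModules] <- 1 / sqrt(sp$nDriverModules)
  actComp <- standardize(as.numeric(crossprod(L, wPW)), cells)
  pairs <- expand.grid(cellId = cells, drugId = drugs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  signal <- sp$activityEffect * actComp[pairs$cellId] +
    sp$mutationEffect * mut$latent[pairs$cellId] +
    sp$drugEffect * fp$latent[pairs$drugId] +
    sp$interactionEffect * actComp[pairs$cellId] * fp$latent[pairs$drugId]
  noiseSdAbs <- sp$noiseSd * stats::sd(signal)
  noise <- withSeed(substreamSeed(sp$seed, "noise"),
                    stats::rnorm(nrow(pairs), sd = noiseSdAbs))
  pairs$lnIC50 <- as.numeric(signal + noise)
  pairs$source <- "synthetic"
  methods::new("SyntheticCohort",
               network = net$network, driverGenes = driverGenes,
               geneSets = geneSets, expression = expression,
               mutations = mut$M, fingerprints = fp$F, pairs = pairs,
               groundTruth = list(
                 latentActivity = L, activityComponent = actComp,
                 mutationLatent = mut$latent, mutationWeights = mut$v,
                 drugLatent = fp$latent, drugWeights = fp$u,
                 pathwayWeights = wPW, driverModules = driverModules,
                 modules = modules, noiselessResponse = as.numeric(signal),
                 noiseSdAbs = noiseSdAbs),
               spec = sp)
}

standardize <- function(x, nm) {
  s <- stats::sd(x)
  stats::setNames(if (s == 0) x - mean(x) else (x - mean(x)) / s, nm)
}

## full-precision numeric TSV (round-trips doubles exactly)
writeNumericTSV <- function(m, path, idColumn = "gene") {
  fm <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(idColumn, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Emits expression.tsv, mutations.tsv, fingerprints.tsv, pairs.tsv,
#' ppi_edges.tsv, drivers.txt, genesets.gmt, ground_truth.json and a
#' manifest.json carrying the generating spec and per-file MD5 checksums.
#' [readFixture()] reproduces the cohort exactly from these files.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisible manifest list.
#' @export
writeFixture <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gt <- cohort@groundTruth
  writeNumericTSV(cohort@expression, file.path(dir, "expression.tsv"))
  writeNumericTSV(cohort@mutations, file.path(dir, "mutations.tsv"))
  fpm <- cohort@fingerprints
  rownames(fpm) <- sprintf("bit%04d", seq_len(nrow(fpm)))
  writeNumericTSV(fpm, file.path(dir, "fingerprints.tsv"), idColumn = "bit")
  pr <- cohort@pairs
  pr$lnIC50 <- sprintf("%.17g", pr$lnIC50)
  utils::write.table(pr, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writePPIEdges(cohort@network, file.path(dir, "ppi_edges.tsv"))
  writeLines(cohort@driverGenes, file.path(dir, "drivers.txt"))
  writeGMT(cohort@geneSets, file.path(dir, "genesets.gmt"))
  jsonlite::write_json(
    list(spec = cohort@spec,
         latentActivity = gt$latentActivity,
         activityComponent = gt$activityComponent,
         mutationLatent = gt$mutationLatent,
         mutationWeights = gt$mutationWeights,
         drugLatent = gt$drugLatent, drugWeights = gt$drugWeights,
         pathwayWeights = gt$pathwayWeights,
         driverModules = gt$driverModules,
         modules = as.list(gt$modules),
         noiselessResponse = gt$noiselessResponse,
         noiseSdAbs = gt$noiseSdAbs),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  files <- c("expression.tsv", "mutations.tsv", "fingerprints.tsv",
             "pairs.tsv", "ppi_edges.tsv", "drivers.txt", "genesets.gmt",
             "ground_truth.json")
  manifest <- list(spec = cohort@spec,
                   checksums = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' @rdname writeFixture
#' @export
readFixture <- function(dir) {
  expression <- readMatrixTSV(file.path(dir, "expression.tsv"))
  mutations <- readMatrixTSV(file.path(dir, "mutations.tsv"))
  fingerprints <- readMatrixTSV(file.path(dir, "fingerprints.tsv"))
  rownames(fingerprints) <- NULL
  pairs <- readPairsTSV(file.path(dir, "pairs.tsv"))
  edges <- utils::read.delim(file.path(dir, "ppi_edges.tsv"),
                             colClasses = "character")
  genes <- rownames(expression)
  A <- Matrix::sparseMatrix(
    i = c(match(edges$geneA, genes), match(edges$geneB, genes)),
    j = c(match(edges$geneB, genes), match(edges$geneA, genes)),
    x = 1, dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes))
  A@x[] <- 1
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  spec <- gt$spec
  methods::new("SyntheticCohort",
               network = methods::new("PPINetwork", nodes = genes, adjacency = A),
               driverGenes = readLines(file.path(dir, "drivers.txt")),
               geneSets = readGMT(file.path(dir, "genesets.gmt")),
               expression = expression, mutations = mutations,
               fingerprints = fingerprints, pairs = pairs,
               groundTruth = list(
                 latentActivity = gt$latentActivity,
                 activityComponent = unlist(gt$activityComponent),
                 mutationLatent = unlist(gt$mutationLatent),
                 mutationWeights = gt$mutationWeights,
                 drugLatent = unlist(gt$drugLatent),
                 drugWeights = gt$drugWeights,
                 pathwayWeights = gt$pathwayWeights,
                 driverModules = gt$driverModules,
                 modules = unlist(gt$modules),
                 noiselessResponse = gt$noiselessResponse,
                 noiseSdAbs = gt$noiseSdAbs),
               spec = spec)
}
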