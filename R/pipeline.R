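#' Characterization stage: driver signals to pathway activity features
#'
#' Runs the pre-training characterization protocol: multi-source edge
#' filtering, largest-component extraction, random-walk-with-restart
#' propagation from the driver seeds, preranked GSEA of the propagation
#' ranking against the gene-set collection, signature selection (ES > 0,
#' FDR < fdrMax), and per-sample ssGSEA activity scoring. Stage-by-stage
#' record counts are collected in `log`; artifacts are written when
#' `outDir` is given.
#'
#' @param edgeRecords data.frame (geneA, geneB, source), or a ready
#'   [PPINetwork-class] to skip edge filtering.
#' @param driverGenes character vector of seed genes.
#' @param geneSets named list of gene sets (e.g. from [readGMT()]).
#' @param expression gene x sample log-scale expression matrix.
#' @param minSources edge-support threshold; default 2.
#' @param beta,tol RWR parameters; defaults 0.9 and 1e-10.
#' @param exponent,nPerm GSEA settings; defaults 0 and 1000. The unweighted
#'   statistic is the stage default because restart-dominated propagation
#'   scores are heavy-tailed (seeds hold most of the mass), which saturates
#'   the weighted running sum and erases the distinction between a fully
#'   enriched pathway and a set containing a single seed; the unweighted
#'   statistic discriminates by the positions of all members.
#' @param esMin,fdrMax signature thresholds; defaults 0 and 0.2.
#' @param alpha ssGSEA exponent; default 0.25.
#' @param seed master seed (GSEA null).
#' @param outDir optional artifact directory.
#' @return list: `network`, `propagation`, `enrichment`, `signature`
#'   ([PathwaySignature-class]), `activity` (pathway x sample), `log`.
#' @export
runCharacterize <- function(edgeRecords, driverGenes, geneSets, expression,
                            minSources = 2, beta = 0.9, tol = 1e-10,
                            exponent = 0, nPerm = 1000L, esMin = 0,
                            fdrMax = 0.2, alpha = 0.25, seed = 1L,
                            outDir = NULL) {
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  net <- stage("filter_edges", {
    if (methods::is(edgeRecords, "PPINetwork")) edgeRecords
    else filterEdges(edgeRecords, minSources = minSources)
  })
  log$edgesKept <- networkEdges(net)
  net <- stage("largest_component", largestComponent(net))
  log$nodesInComponent <- length(net)
  prop <- stage("propagation", {
    tm <- normalizeColumns(net)
    c0 <- makeSeedVector(net, driverGenes)
    log$seedsMapped <- sum(c0 > 0)
    log$seedsUnmapped <- attr(c0, "nUnmapped")
    propagate(tm, c0, beta = beta, tol = tol)
  })
  log$propagationIterations <- prop$iterations
  enr <- stage("gsea", {
    suppressWarnings(gsea(rankedList(prop$scores), geneSets,
                          exponent = exponent, nPerm = nPerm,
                          seed = substreamSeed(seed, "gsea")))
  })
  sig <- stage("select_signature", selectSignature(enr, esMin, fdrMax))
  log$pathwaysSelected <- length(sig)
  act <- stage("activity_matrix",
               activityMatrix(expression, sig, geneSets = geneSets,
                              alpha = alpha))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writePropagationScores(prop$scores, file.path(outDir, "propagation.tsv"))
    utils::write.table(signatureTable(sig), file.path(outDir, "signature.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeActivityMatrix(act, file.path(outDir, "activity.tsv"))
    jsonlite::write_json(log, file.path(outDir, "characterize_log.json"),
                         auto_unbox = TRUE)
  }
  list(network = net, propagation = prop, enrichment = enr, signature = sig,
       activity = act, log = log)
}

#' Full protocol: characterize, split, train end-to-end, evaluate
#'
#' Convenience orchestration over a [SyntheticCohort-class] or equivalent
#' raw inputs: runs [runCharacterize()], assembles features, splits the
#' pair table, optionally grid-searches autoencoder widths, trains the
#' model end to end, and reports test-set metrics. A machine-readable run
#' manifest (config, seed, stage counts, metrics) is returned and, when
#' `outDir` is given, written together with the model checkpoint.
#'
#' @param cohort a [SyntheticCohort-class] (or list with fields `network`,
#'   `driverGenes`, `geneSets`, `expression`, `mutations`, `fingerprints`,
#'   `pairs`).
#' @param strategy split strategy; default "mix".
#' @param config training config overrides (see [trainEndToEnd()]).
#' @param mutWidths,drugWidths autoencoder widths as c(h1, h2, bottleneck);
#'   defaults scale with the input dimension (h1 ~ input/2 capped at 300,
#'   bottleneck 30 capped at h2).
#' @param pretrain if TRUE, select autoencoder widths by
#'   [pretrainAutoencoder()] grid search before end-to-end training.
#' @param aeWarmEpochs reconstruction-only pretraining epochs for both
#'   autoencoders (at the chosen widths, on training-partition cells and
#'   drugs only) before end-to-end training; 0 disables. Default 20.
#'   Warm-started embeddings are stable from the first end-to-end epoch,
#'   which keeps the validation loss informative for early stopping — with
#'   fresh encoders the embedding spaces drift early and a near-initial
#'   state can spuriously hold the best validation loss under entity-held-out
#'   splits, truncating training.
#' @param characterizeArgs extra arguments passed to [runCharacterize()].
#' @param seed master seed.
#' @param outDir optional artifact directory.
#' @return list: `model`, `signature`, `activity`, `split`, `metrics`
#'   (test-set pcc/rmse/auroc/f1), `manifest`.
#' @export
runFull <- function(cohort, strategy = "mix", config = list(),
                    mutWidths = NULL, drugWidths = NULL, pretrain = FALSE,
                    aeWarmEpochs = 20L, characterizeArgs = list(), seed = 1L,
                    outDir = NULL) {
  if (methods::is(cohort, "SyntheticCohort"))
    cohort <- list(network = cohort@network, driverGenes = cohort@driverGenes,
                   geneSets = cohort@geneSets, expression = cohort@expression,
                   mutations = cohort@mutations,
                   fingerprints = cohort@fingerprints, pairs = cohort@pairs)
  ch <- do.call(runCharacterize,
                c(list(edgeRecords = cohort$network,
                       driverGenes = cohort$driverGenes,
                       geneSets = cohort$geneSets,
                       expression = cohort$expression,
                       seed = substreamSeed(seed, "characterize")),
                  characterizeArgs))
  features <- list(activity = ch$activity, mutations = cohort$mutations,
                   fingerprints = cohort$fingerprints)
  sp <- splitPairs(cohort$pairs, strategy,
                   seed = substreamSeed(seed, "split"))
  defWidths <- function(d) {
    h1 <- min(300L, max(4L, floor(d / 2)))
    h2 <- min(100L, max(2L, floor(h1 / 3)))
    b <- min(30L, h2)
    c(h1, h2, b)
  }
  if (isTRUE(pretrain)) {
    gridFor <- function(d) {
      w <- defWidths(d)
      list(h1 = unique(c(w[1], floor(w[1] / 2))),
           h2 = unique(c(w[2], floor(w[2] / 2))),
           bottleneck = unique(c(w[3], floor(w[3] / 2))))
    }
    mutWidths <- unlist(pretrainAutoencoder(
      t(cohort$mutations), grid = gridFor(nrow(cohort$mutations)),
      seed = substreamSeed(seed, "pretrainMut"))$spec[c("h1", "h2", "bottleneck")])
    drugWidths <- unlist(pretrainAutoencoder(
      t(cohort$fingerprints), grid = gridFor(nrow(cohort$fingerprints)),
      seed = substreamSeed(seed, "pretrainDrug"))$spec[c("h1", "h2", "bottleneck")])
  }
  mutWidths <- mutWidths %||% defWidths(nrow(cohort$mutations))
  drugWidths <- drugWidths %||% defWidths(nrow(cohort$fingerprints))
  model <- buildModel(
    signaturePathways = rownames(ch$activity),
    mutSpec = list(inputDim = nrow(cohort$mutations), h1 = mutWidths[1],
                   h2 = mutWidths[2], bottleneck = mutWidths[3]),
    drugSpec = list(inputDim = nrow(cohort$fingerprints), h1 = drugWidths[1],
                    h2 = drugWidths[2], bottleneck = drugWidths[3]),
    seed = substreamSeed(seed, "model"))
  if (aeWarmEpochs > 0) {
    # reconstruction-only warm start on training-partition entities
    trainCells <- unique(sp$train$cellId)
    trainDrugs <- unique(sp$train$drugId)
    model@mutAE <- trainAutoencoder(
      model@mutAE, t(cohort$mutations[, trainCells, drop = FALSE]),
      epochs = aeWarmEpochs, batchSize = 64L, lr = 1e-3,
      seed = substreamSeed(seed, "warmMut"))$ae
    model@drugAE <- trainAutoencoder(
      model@drugAE, t(cohort$fingerprints[, trainDrugs, drop = FALSE]),
      epochs = aeWarmEpochs, batchSize = 64L, lr = 1e-3,
      seed = substreamSeed(seed, "warmDrug"))$ae
  }
  cfg <- utils::modifyList(list(seed = substreamSeed(seed, "train")), config)
  valMonitor <- sp$val
  if (strategy == "both") {
    # The val x val block alone is tiny (10% of cells times 10% of drugs)
    # and statistically uninformative for early stopping. Monitor instead
    # every pair that involves a validation entity and no test entity and
    # is not a training (train x train) pair: val x val plus the
    # singly-unseen val x train and train x val pairs. Test pairs remain
    # doubly unseen and training data is unchanged.
    ac <- sp$assignments$cell[cohort$pairs$cellId]
    ad <- sp$assignments$drug[cohort$pairs$drugId]
    keep <- ac != "test" & ad != "test" & !(ac == "train" & ad == "train") &
      (ac == "val" | ad == "val")
    valMonitor <- cohort$pairs[keep, , drop = FALSE]
  }
  model <- trainEndToEnd(model, sp$train, valMonitor, features, cfg)
  tbt <- pairBatch(sp$test, features)
  predT <- modelForward(model, tbt$A, tbt$Rc, tbt$Rd)$sPred
  rm <- regressionMetrics(predT, tbt$s)
  qc <- tryCatch(quartileClassification(predT, tbt$s),
                 error = function(e) list(auroc = NA_real_, f1 = NA_real_))
  metrics <- list(pcc = rm$pcc, rmse = rm$rmse, auroc = qc$auroc, f1 = qc$f1,
                  n = nrow(sp$test))
  manifest <- list(seed = seed, strategy = strategy, config = model@config,
                   aeWarmEpochs = as.integer(aeWarmEpochs),
                   mutWidths = as.integer(mutWidths),
                   drugWidths = as.integer(drugWidths),
                   characterizeLog = ch$log,
                   splitSizes = list(train = nrow(sp$train),
                                     val = nrow(sp$val), test = nrow(sp$test),
                                     discarded = sp$nDiscarded),
                   epochsRun = nrow(model@history), metrics = metrics,
                   packageVersion = as.character(utils::packageVersion("driverSigDR")))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    saveModel(model, file.path(outDir, "model.rds"))
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(model = model, signature = ch$signature, activity = ch$activity,
       split = sp, metrics = metrics, manifest = manifest)
}

#' Read a run configuration from YAML
#'
#' Loads a YAML file whose top-level keys mirror the arguments of
#' [runFull()] (`strategy`, `seed`, `config` for training settings,
#' `characterizeArgs` for characterization settings, `mutWidths`,
#' `drugWidths`, `pretrain`), merges it over the package defaults, and
#' validates the ranges that matter. Command-line flags are expected to
#' win over file values; pass them through `overrides`.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file's values.
#' @return a validated configuration list.
#' @export
readRunConfig <- function(path, overrides = list()) {
  stopIfNot(file.exists(path), paste("config file not found:", path))
  cfg <- yaml::read_yaml(path) %||% list()
  stopIfNot(is.list(cfg), "config must be a YAML mapping")
  known <- c("strategy", "seed", "config", "characterizeArgs",
             "mutWidths", "drugWidths", "pretrain")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, overrides)
  if (!is.null(cfg$strategy))
    stopIfNot(cfg$strategy %in% c("mix", "cell", "drug", "both"),
              "strategy must be one of mix/cell/drug/both")
  if (!is.null(cfg$config$lr)) stopIfNot(cfg$config$lr > 0, "lr must be > 0")
  if (!is.null(cfg$config$patience))
    stopIfNot(cfg$config$patience >= 1, "patience must be >= 1")
  if (!is.null(cfg$characterizeArgs$fdrMax))
    stopIfNot(cfg$characterizeArgs$fdrMax > 0 && cfg$characterizeArgs$fdrMax <= 1,
              "fdrMax must be in (0, 1]")
  cfg
}
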