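#' Build the drug-sensitivity model (two autoencoders + feedforward net)
#'
#' The feedforward regressor takes the concatenation of the pathway
#' activity vector and the two autoencoder bottleneck embeddings; it has
#' two hidden layers, each as wide as its input, with batch normalization
#' and ReLU, and a single linear output neuron (unbounded LN IC50).
#'
#' @param signaturePathways character vector naming the activity features.
#' @param mutSpec,drugSpec autoencoder width lists (see [buildAutoencoder()]);
#'   `inputDim` must match the mutation / fingerprint feature counts.
#' @param seed integer seed for all weight initialization.
#' @return an untrained [DeepSensModel-class].
#' @export
buildModel <- function(signaturePathways, mutSpec, drugSpec, seed = 1L) {
  stopIfNot(length(signaturePathways) >= 1, "need >= 1 signature pathway")
  mutAE <- buildAutoencoder(mutSpec, seed = substreamSeed(seed, "mutAE"))
  drugAE <- buildAutoencoder(drugSpec, seed = substreamSeed(seed, "drugAE"))
  pIn <- length(signaturePathways) + mutAE$spec$bottleneck + drugAE$spec$bottleneck
  fnn <- mlpBuild(c(pIn, pIn, pIn, 1L),
                  activations = c("relu", "relu", "linear"),
                  batchNorm = c(TRUE, TRUE, FALSE),
                  seed = substreamSeed(seed, "fnn"))
  methods::new("DeepSensModel", mutAE = mutAE, drugAE = drugAE, fnn = fnn,
               signaturePathways = as.character(signaturePathways),
               config = list(seed = seed),
               history = data.frame())
}

#' Forward pass of the full model (evaluation mode)
#'
#' @param model a [DeepSensModel-class].
#' @param A samples x pathways activity matrix.
#' @param Rc samples x driver-genes binary mutation matrix.
#' @param Rd samples x bits binary fingerprint matrix.
#' @return list: `sPred` (length-n predictions), `rcRecon`, `rdRecon`
#'   (reconstruction probabilities in (0,1)), `zC`, `zD` (embeddings).
#' @export
modelForward <- function(model, A, Rc, Rd) {
  n <- nrow(A)
  stopIfNot(ncol(A) == length(model@signaturePathways),
            "activity block width mismatch")
  stopIfNot(nrow(Rc) == n && nrow(Rd) == n, "batch lengths differ")
  if (ncol(Rc) != model@mutAE$spec$inputDim)
    stop("mutation block width mismatch", call. = FALSE)
  if (ncol(Rd) != model@drugAE$spec$inputDim)
    stop("fingerprint block width mismatch", call. = FALSE)
  fc <- aeForward(model@mutAE, Rc, training = FALSE)
  fd <- aeForward(model@drugAE, Rd, training = FALSE)
  fin <- cbind(A, fc$z, fd$z)
  ff <- mlpForward(model@fnn, fin, training = FALSE)
  list(sPred = as.numeric(ff$out), rcRecon = fc$recon, rdRecon = fd$recon,
       zC = fc$z, zD = fd$z)
}

#' Unified training loss: prediction MSE + weighted reconstruction BCEs
#'
#' mean((sObs - sPred)^2) + lambdaC * BCE(Rc, rcRecon) +
#' lambdaD * BCE(Rd, rdRecon), each BCE averaged over all matrix entries.
#'
#' @param sObs,sPred observed and predicted LN IC50 vectors.
#' @param Rc,rcRecon binary mutation targets and reconstruction
#'   probabilities (must lie strictly inside (0,1)).
#' @param Rd,rdRecon fingerprint targets and reconstruction probabilities.
#' @param lambdaC,lambdaD reconstruction weights; default 1.
#' @return scalar loss (>= 0).
#' @export
unifiedLoss <- function(sObs, sPred, Rc, rcRecon, Rd, rdRecon,
                        lambdaC = 1, lambdaD = 1) {
  stopIfNot(length(sObs) == length(sPred), "prediction length mismatch")
  stopIfNot(lambdaC >= 0 && lambdaD >= 0, "lambda weights must be >= 0")
  if (any(rcRecon <= 0 | rcRecon >= 1) || any(rdRecon <= 0 | rdRecon >= 1))
    stop("reconstruction probabilities must lie strictly inside (0,1)",
         call. = FALSE)
  mean((sObs - sPred)^2) + lambdaC * meanBCE(Rc, rcRecon) +
    lambdaD * meanBCE(Rd, rdRecon)
}

## assemble per-pair feature blocks (samples in pair order, rows)
pairBatch <- function(pairs, features) {
  list(A = t(features$activity)[pairs$cellId, , drop = FALSE],
       Rc = t(features$mutations)[pairs$cellId, , drop = FALSE],
       Rd = t(features$fingerprints)[pairs$drugId, , drop = FALSE],
       s = pairs$lnIC50)
}

evalLoss <- function(model, batch, lambdaC, lambdaD) {
  out <- modelForward(model, batch$A, batch$Rc, batch$Rd)
  unifiedLoss(batch$s, out$sPred, batch$Rc, out$rcRecon, batch$Rd,
              out$rdRecon, lambdaC, lambdaD)
}

#' End-to-end training with Adam and early stopping
#'
#' Minimizes the unified loss over shuffled minibatches. After each epoch
#' the validation loss (evaluation mode) is computed; training stops when
#' it has not improved for `patience` consecutive epochs, or at
#' `maxEpochs`. The state with the best validation loss is returned.
#'
#' @param model an untrained [DeepSensModel-class] from [buildModel()].
#' @param trainPairs,valPairs disjoint pair tables (cellId, drugId, lnIC50).
#' @param features list with `activity` (pathway x cell), `mutations`
#'   (driver x cell), `fingerprints` (bit x drug); column names must cover
#'   the pairs' cells and drugs.
#' @param config list: `lr` (1e-3), `batchSize` (1024), `maxEpochs` (100),
#'   `patience` (10), `lambdaC` (1), `lambdaD` (1), `seed` (1).
#' @return the trained [DeepSensModel-class]; `trainingHistory()` gives the
#'   per-epoch losses.
#' @export
trainEndToEnd <- function(model, trainPairs, valPairs, features,
                          config = list()) {
  cfg <- utils::modifyList(list(lr = 1e-3, batchSize = 1024L, maxEpochs = 100L,
                                patience = 10L, lambdaC = 1, lambdaD = 1,
                                seed = 1L), config)
  stopIfNot(nrow(trainPairs) > 0 && nrow(valPairs) > 0,
            "train and validation sets must be non-empty")
  stopIfNot(cfg$patience >= 1 && cfg$lr > 0, "invalid config")
  trainKey <- paste(trainPairs$cellId, trainPairs$drugId)
  stopIfNot(!any(trainKey %in% paste(valPairs$cellId, valPairs$drugId)),
            "train and validation pairs overlap")
  valBatch <- pairBatch(valPairs, features)
  tb <- pairBatch(trainPairs, features)
  n <- nrow(trainPairs)
  mutAE <- model@mutAE; drugAE <- model@drugAE; fnn <- model@fnn
  stMutE <- adamInitNet(mutAE$encoder); stMutD <- adamInitNet(mutAE$decoder)
  stDrugE <- adamInitNet(drugAE$encoder); stDrugD <- adamInitNet(drugAE$decoder)
  stF <- adamInitNet(fnn)
  lC <- cfg$lambdaC; lD <- cfg$lambdaD
  p <- length(model@signaturePathways)
  bc <- mutAE$spec$bottleneck; bd <- drugAE$spec$bottleneck
  t <- 0L
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric())
  bestVal <- Inf
  best <- list(mutAE = mutAE, drugAE = drugAE, fnn = fnn)
  bad <- 0L
  withSeed(substreamSeed(cfg$seed, "e2e-shuffle"), {
    for (ep in seq_len(cfg$maxEpochs)) {
      perm <- sample.int(n)
      epochLoss <- 0
      for (s0 in seq(1, n, by = cfg$batchSize)) {
        idx <- perm[s0:min(s0 + cfg$batchSize - 1, n)]
        Ab <- tb$A[idx, , drop = FALSE]
        Rcb <- tb$Rc[idx, , drop = FALSE]
        Rdb <- tb$Rd[idx, , drop = FALSE]
        sb <- tb$s[idx]
        nb <- length(idx)
        feC <- mlpForward(mutAE$encoder, Rcb, TRUE); mutAE$encoder <- feC$net
        fdC <- mlpForward(mutAE$decoder, feC$out, TRUE); mutAE$decoder <- fdC$net
        feD <- mlpForward(drugAE$encoder, Rdb, TRUE); drugAE$encoder <- feD$net
        fdD <- mlpForward(drugAE$decoder, feD$out, TRUE); drugAE$decoder <- fdD$net
        fin <- cbind(Ab, feC$out, feD$out)
        ff <- mlpForward(fnn, fin, TRUE); fnn <- ff$net
        sPred <- as.numeric(ff$out)
        loss <- mean((sb - sPred)^2) + lC * meanBCE(Rcb, fdC$out) +
          lD * meanBCE(Rdb, fdD$out)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", ep, ", batch starting at ", s0,
               call. = FALSE)
        epochLoss <- epochLoss + loss * nb
        # prediction head
        dS <- matrix(2 * (sPred - sb) / nb, ncol = 1)
        bF <- mlpBackward(fnn, ff$caches, dS, topIsPre = TRUE)
        dzC <- bF$dX[, p + seq_len(bc), drop = FALSE]
        dzD <- bF$dX[, p + bc + seq_len(bd), drop = FALSE]
        # reconstruction heads (gradients on decoder output logits)
        bDecC <- mlpBackward(mutAE$decoder, fdC$caches,
                             lC * (fdC$out - Rcb) / length(Rcb), topIsPre = TRUE)
        bEncC <- mlpBackward(mutAE$encoder, feC$caches, bDecC$dX + dzC)
        bDecD <- mlpBackward(drugAE$decoder, fdD$caches,
                             lD * (fdD$out - Rdb) / length(Rdb), topIsPre = TRUE)
        bEncD <- mlpBackward(drugAE$encoder, feD$caches, bDecD$dX + dzD)
        t <- t + 1L
        u <- adamStepNet(fnn, bF$grads, stF, cfg$lr, t)
        fnn <- u$net; stF <- u$state
        u <- adamStepNet(mutAE$decoder, bDecC$grads, stMutD, cfg$lr, t)
        mutAE$decoder <- u$net; stMutD <- u$state
        u <- adamStepNet(mutAE$encoder, bEncC$grads, stMutE, cfg$lr, t)
        mutAE$encoder <- u$net; stMutE <- u$state
        u <- adamStepNet(drugAE$decoder, bDecD$grads, stDrugD, cfg$lr, t)
        drugAE$decoder <- u$net; stDrugD <- u$state
        u <- adamStepNet(drugAE$encoder, bEncD$grads, stDrugE, cfg$lr, t)
        drugAE$encoder <- u$net; stDrugE <- u$state
      }
      cur <- model
      cur@mutAE <- mutAE; cur@drugAE <- drugAE; cur@fnn <- fnn
      valLoss <- evalLoss(cur, valBatch, lC, lD)
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epochLoss / n,
                                     valLoss = valLoss))
      if (valLoss < bestVal) {
        bestVal <- valLoss
        best <- list(mutAE = mutAE, drugAE = drugAE, fnn = fnn)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) break
      }
    }
  })
  model@mutAE <- best$mutAE
  model@drugAE <- best$drugAE
  model@fnn <- best$fnn
  model@config <- cfg
  model@history <- hist
  model
}

#' Batch inference over a pair table
#'
#' Deterministic evaluation-mode predictions in input row order. Pairs
#' whose cell or drug lacks features are reported in the `rejects`
#' attribute (with reasons), not silently dropped.
#'
#' @param model a trained [DeepSensModel-class].
#' @param features feature list (see [trainEndToEnd()]).
#' @param pairs data.frame with `cellId`, `drugId`.
#' @return numeric predictions for the predictable pairs, named by
#'   `cellId:drugId`, with attribute `rejects` (data.frame, possibly empty).
#' @export
predictPairs <- function(model, features, pairs) {
  okCell <- pairs$cellId %in% colnames(features$activity) &
    pairs$cellId %in% colnames(features$mutations)
  okDrug <- pairs$drugId %in% colnames(features$fingerprints)
  ok <- okCell & okDrug
  if (!any(ok)) stop("no pair has complete features", call. = FALSE)
  rejects <- data.frame(
    cellId = pairs$cellId[!ok], drugId = pairs$drugId[!ok],
    reason = ifelse(!okCell[!ok], "missing cell features",
                    "missing drug features"))
  b <- pairBatch(pairs[ok, , drop = FALSE], features)
  out <- modelForward(model, b$A, b$Rc, b$Rd)
  preds <- stats::setNames(out$sPred,
                           paste(pairs$cellId[ok], pairs$drugId[ok], sep = ":"))
  attr(preds, "rejects") <- rejects
  preds
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive of all weights, normalization
#' statistics, specs, config, history and signature pathway names; a
#' reloaded model reproduces predictions bitwise.
#'
#' @param model a [DeepSensModel-class]
#' @param path checkpoint file path
#' @return `loadModel()`: the restored [DeepSensModel-class].
#' @export
saveModel <- function(model, path) {
  payload <- list(schema = "driverSigDR-checkpoint-1",
                  mutAE = model@mutAE, drugAE = model@drugAE, fnn = model@fnn,
                  signaturePathways = model@signaturePathways,
                  config = model@config, history = model@history)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  payload <- readRDS(path)
  stopIfNot(identical(payload$schema, "driverSigDR-checkpoint-1"),
            "unrecognized checkpoint schema")
  methods::new("DeepSensModel", mutAE = payload$mutAE,
               drugAE = payload$drugAE, fnn = payload$fnn,
               signaturePathways = payload$signaturePathways,
               config = payload$config, history = payload$history)
}

#' Hyperparameter grid search for end-to-end training
#'
#' Trains every learning-rate x batch-size combination for a fixed number
#' of epochs (no early stopping) and ranks configurations by held-out RMSE
#' ascending, breaking ties by PCC descending.
#'
#' @param model untrained [DeepSensModel-class] template (re-initialized per
#'   run from its seed).
#' @param trainPairs,valPairs,testPairs pair tables; `testPairs` drives the
#'   ranking.
#' @param features feature list.
#' @param lrs,batchSizes grids; defaults (1e-2, 1e-3, 1e-4) and
#'   (256, 512, 1024).
#' @param epochs epochs per combination; default 50.
#' @param config base config entries (lambdas, seed).
#' @return list: `config` (best, merged into the base), `table` (per-combo
#'   RMSE/PCC, ranked).
#' @export
gridSearchTrain <- function(model, trainPairs, valPairs, testPairs, features,
                            lrs = c(1e-2, 1e-3, 1e-4),
                            batchSizes = c(256L, 512L, 1024L),
                            epochs = 50L, config = list()) {
  stopIfNot(length(lrs) > 0 && length(batchSizes) > 0, "grids must be non-empty")
  combos <- expand.grid(lr = lrs, batchSize = batchSizes)
  testBatch <- pairBatch(testPairs, features)
  rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    cfg <- utils::modifyList(config,
                             list(lr = combos$lr[k],
                                  batchSize = as.integer(combos$batchSize[k]),
                                  maxEpochs = as.integer(epochs),
                                  patience = as.integer(epochs)))
    fit <- tryCatch(trainEndToEnd(model, trainPairs, valPairs, features, cfg),
                    error = function(e) NULL)
    if (is.null(fit)) {
      rows[[k]] <- data.frame(lr = combos$lr[k], batchSize = combos$batchSize[k],
                              rmse = Inf, pcc = -Inf)
      next
    }
    pred <- modelForward(fit, testBatch$A, testBatch$Rc, testBatch$Rd)$sPred
    m <- regressionMetrics(pred, testBatch$s)
    rows[[k]] <- data.frame(lr = combos$lr[k], batchSize = combos$batchSize[k],
                            rmse = m$rmse, pcc = m$pcc)
  }
  tab <- do.call(rbind, rows)
  if (all(!is.finite(tab$rmse))) stop("all grid runs diverged", call. = FALSE)
  ord <- order(tab$rmse, -tab$pcc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(config = utils::modifyList(config, list(lr = tab$lr[1],
                                               batchSize = as.integer(tab$batchSize[1]))),
       table = tab)
}
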