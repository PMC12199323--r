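#' Build a symmetric autoencoder for binary feature vectors
#'
#' Three-layer encoder (two hidden layers and one bottleneck), each dense
#' layer followed by batch normalization and ReLU, mirrored by a decoder
#' whose final layer applies a sigmoid so reconstructions lie in (0, 1).
#' Weight initialization is He-uniform from the given seed.
#'
#' @param spec list with `inputDim`, `h1`, `h2`, `bottleneck`
#'   (inputDim > h1 >= h2 >= bottleneck >= 1).
#' @param seed integer seed for weight initialization.
#' @return an autoencoder state list (`spec`, `encoder`, `decoder`).
#' @export
buildAutoencoder <- function(spec, seed = 1L) {
  d <- as.integer(unlist(spec[c("inputDim", "h1", "h2", "bottleneck")]))
  stopIfNot(length(d) == 4 && all(is.finite(d)),
            "spec needs inputDim, h1, h2, bottleneck")
  stopIfNot(d[1] > d[2] && d[2] >= d[3] && d[3] >= d[4] && d[4] >= 1,
            "invalid widths: need inputDim > h1 >= h2 >= bottleneck >= 1")
  list(
    spec = list(inputDim = d[1], h1 = d[2], h2 = d[3], bottleneck = d[4]),
    encoder = mlpBuild(d, activations = c("relu", "relu", "relu"),
                       batchNorm = c(TRUE, TRUE, TRUE),
                       seed = substreamSeed(seed, "encoder")),
    decoder = mlpBuild(rev(d), activations = c("relu", "relu", "sigmoid"),
                       batchNorm = c(TRUE, TRUE, FALSE),
                       seed = substreamSeed(seed, "decoder"))
  )
}

#' Autoencoder forward pass
#'
#' @param ae autoencoder state from [buildAutoencoder()].
#' @param X samples x features binary matrix.
#' @param training use batch statistics (TRUE) or running statistics.
#' @return list with `z` (bottleneck activations), `recon` (in (0,1)), and
#'   internal caches/updated state for training.
#' @export
aeForward <- function(ae, X, training = FALSE) {
  stopIfNot(ncol(X) == ae$spec$inputDim, "feature dimension mismatch")
  fe <- mlpForward(ae$encoder, X, training)
  fd <- mlpForward(ae$decoder, fe$out, training)
  list(z = fe$out, recon = fd$out,
       encCache = fe$caches, decCache = fd$caches,
       ae = list(spec = ae$spec, encoder = fe$net, decoder = fd$net))
}

#' Autoencoder parameter count
#'
#' Closed-form check target: every dense layer contributes in*out weights +
#' out biases, every batch-norm layer 2*out parameters.
#'
#' @param ae autoencoder state.
#' @return total learnable parameter count.
#' @export
aeParamCount <- function(ae) mlpParamCount(ae$encoder) + mlpParamCount(ae$decoder)

#' Train an autoencoder by reconstruction BCE with Adam
#'
#' @param ae autoencoder state.
#' @param X samples x features binary matrix.
#' @param epochs number of passes; default 50.
#' @param batchSize minibatch size; default 64.
#' @param lr Adam learning rate; default 1e-3.
#' @param seed shuffling seed.
#' @param valX optional held-out matrix; per-epoch validation BCE recorded.
#' @return list: `ae` (trained), `history` (data.frame epoch/trainBCE/valBCE).
#' @export
trainAutoencoder <- function(ae, X, epochs = 50L, batchSize = 64L, lr = 1e-3,
                             seed = 1L, valX = NULL) {
  stopIfNot(all(X %in% c(0, 1)), "features must be binary")
  n <- nrow(X)
  stateE <- adamInitNet(ae$encoder)
  stateD <- adamInitNet(ae$decoder)
  t <- 0L
  hist <- data.frame(epoch = integer(), trainBCE = numeric(),
                     valBCE = numeric())
  withSeed(substreamSeed(seed, "ae-shuffle"), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + batchSize - 1, n)]
        xb <- X[idx, , drop = FALSE]
        fe <- mlpForward(ae$encoder, xb, training = TRUE)
        ae$encoder <- fe$net
        fd <- mlpForward(ae$decoder, fe$out, training = TRUE)
        ae$decoder <- fd$net
        p <- fd$out
        loss <- meanBCE(xb, p)
        epochLoss <- epochLoss + loss * length(idx)
        # gradient of mean BCE w.r.t. decoder output logits
        dLogit <- (p - xb) / length(p)
        bd <- mlpBackward(ae$decoder, fd$caches, dLogit, topIsPre = TRUE)
        be <- mlpBackward(ae$encoder, fe$caches, bd$dX)
        t <- t + 1L
        u <- adamStepNet(ae$decoder, bd$grads, stateD, lr, t)
        ae$decoder <- u$net; stateD <- u$state
        u <- adamStepNet(ae$encoder, be$grads, stateE, lr, t)
        ae$encoder <- u$net; stateE <- u$state
      }
      valBCE <- NA_real_
      if (!is.null(valX))
        valBCE <- meanBCE(valX, aeForward(ae, valX, training = FALSE)$recon)
      hist <- rbind(hist, data.frame(epoch = ep, trainBCE = epochLoss / n,
                                     valBCE = valBCE))
    }
  })
  list(ae = ae, history = hist)
}

#' Grid search over autoencoder widths by held-out reconstruction BCE
#'
#' Trains every (h1, h2, bottleneck) combination for a fixed number of
#' epochs and returns the spec with the lowest reconstruction BCE on the
#' held-out partition; ties are broken toward fewer parameters.
#'
#' @param features samples x features binary matrix.
#' @param grid list with numeric vectors `h1`, `h2`, `bottleneck`; default
#'   h1 in (300, 200, 100), h2 in (100, 50, 30), bottleneck in (30, 20, 10).
#'   Combinations violating inputDim > h1 >= h2 >= bottleneck are skipped.
#' @param epochs training epochs per combination; default 50.
#' @param holdout fraction of samples held out for selection; default 0.2.
#' @param seed master seed (split, initialization, shuffling).
#' @param lr,batchSize optimizer settings.
#' @return list: `spec` (best), `table` (per-combination BCE), `ae` (the
#'   trained best autoencoder).
#' @export
pretrainAutoencoder <- function(features,
                                grid = list(h1 = c(300, 200, 100),
                                            h2 = c(100, 50, 30),
                                            bottleneck = c(30, 20, 10)),
                                epochs = 50L, holdout = 0.2, seed = 1L,
                                lr = 1e-3, batchSize = 64L) {
  stopIfNot(all(features %in% c(0, 1)), "features must be binary")
  stopIfNot(length(grid$h1) > 0 && length(grid$h2) > 0 &&
              length(grid$bottleneck) > 0, "grid must be non-empty")
  n <- nrow(features)
  inputDim <- ncol(features)
  idxVal <- withSeed(substreamSeed(seed, "pretrain-split"),
                     sort(sample.int(n, max(1, round(holdout * n)))))
  trainX <- features[-idxVal, , drop = FALSE]
  valX <- features[idxVal, , drop = FALSE]
  combos <- expand.grid(h1 = grid$h1, h2 = grid$h2,
                        bottleneck = grid$bottleneck)
  ok <- inputDim > combos$h1 & combos$h1 >= combos$h2 &
    combos$h2 >= combos$bottleneck & combos$bottleneck >= 1
  combos <- combos[ok, , drop = FALSE]
  stopIfNot(nrow(combos) > 0, "no valid width combination for this input size")
  res <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    spec <- list(inputDim = inputDim, h1 = combos$h1[k], h2 = combos$h2[k],
                 bottleneck = combos$bottleneck[k])
    ae <- buildAutoencoder(spec, seed = substreamSeed(seed, paste0("grid", k)))
    fit <- trainAutoencoder(ae, trainX, epochs = epochs,
                            batchSize = batchSize, lr = lr,
                            seed = substreamSeed(seed, paste0("fit", k)),
                            valX = NULL)
    bce <- meanBCE(valX, aeForward(fit$ae, valX, training = FALSE)$recon)
    res[[k]] <- list(spec = spec, bce = bce, params = aeParamCount(fit$ae),
                     ae = fit$ae)
  }
  tab <- data.frame(h1 = combos$h1, h2 = combos$h2,
                    bottleneck = combos$bottleneck,
                    heldOutBCE = vapply(res, `[[`, numeric(1), "bce"),
                    nParams = vapply(res, `[[`, numeric(1), "params"))
  best <- order(tab$heldOutBCE, tab$nParams)[1]
  list(spec = res[[best]]$spec, table = tab, ae = res[[best]]$ae)
}
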