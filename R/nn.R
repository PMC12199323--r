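## Minimal dense-network machinery: affine layers with optional batch
## normalization, ReLU/sigmoid/linear activations, manual backprop and the
## Adam optimizer. Samples are rows; weights W are (in x out).
##
## Layer order within a block: affine -> batch norm -> activation, matching
## the usual dense+BN+ReLU stack. Batch statistics use the biased variance;
## running statistics (momentum 0.9) are used in evaluation mode.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

## He-uniform initialization; draws from the *current* RNG stream so the
## caller controls determinism with one seed.
nnDense <- function(nin, nout) {
  lim <- sqrt(6 / nin)
  list(W = matrix(stats::runif(nin * nout, -lim, lim), nin, nout),
       b = numeric(nout))
}

#' @noRd
mlpBuild <- function(dims, activations, batchNorm, seed = NULL) {
  L <- length(dims) - 1
  stopifnot(length(activations) == L, length(batchNorm) == L)
  build <- function() {
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      layer <- nnDense(dims[l], dims[l + 1])
      layer$act <- activations[l]
      if (batchNorm[l])
        layer$bn <- list(gamma = rep(1, dims[l + 1]),
                         beta = numeric(dims[l + 1]),
                         runMean = numeric(dims[l + 1]),
                         runVar = rep(1, dims[l + 1]))
      layers[[l]] <- layer
    }
    list(layers = layers, dims = dims)
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

applyAct <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z,
         stop("unknown activation: ", act))
}

## Forward pass. training=TRUE uses batch statistics and records a cache
## for backprop (and, as a side effect, the updated running statistics that
## the caller must write back into the network).
mlpForward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  out <- X
  for (l in seq_along(net$layers)) {
    layer <- net$layers[[l]]
    Z <- out %*% layer$W
    Z <- sweep(Z, 2, layer$b, "+")
    cache <- list(X = out)
    if (!is.null(layer$bn)) {
      if (training) {
        mu <- colMeans(Z)
        va <- colMeans(Z^2) - mu^2            # biased batch variance
        n <- nrow(Z)
        unb <- if (n > 1) va * n / (n - 1) else va
        layer$bn$runMean <- BN_MOMENTUM * layer$bn$runMean + (1 - BN_MOMENTUM) * mu
        layer$bn$runVar <- BN_MOMENTUM * layer$bn$runVar + (1 - BN_MOMENTUM) * unb
        net$layers[[l]] <- layer
      } else {
        mu <- layer$bn$runMean
        va <- layer$bn$runVar
      }
      xhat <- sweep(sweep(Z, 2, mu, "-"), 2, sqrt(va + BN_EPS), "/")
      Y <- sweep(sweep(xhat, 2, layer$bn$gamma, "*"), 2, layer$bn$beta, "+")
      cache$xhat <- xhat; cache$va <- va
    } else {
      Y <- Z
    }
    out <- applyAct(Y, layer$act)
    cache$preAct <- Y; cache$out <- out
    caches[[l]] <- cache
  }
  list(out = out, caches = caches, net = net)
}

## Backward pass: dTop is the loss gradient w.r.t. the final activation
## output, or w.r.t. the final pre-activation when topIsPre=TRUE (used to
## fuse sigmoid+BCE and linear+MSE for numerical stability). evalMode=TRUE
## treats batch-norm statistics as constants (inference-time gradients,
## e.g. for integrated gradients).
mlpBackward <- function(net, caches, dTop, topIsPre = FALSE, evalMode = FALSE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  d <- dTop
  for (l in rev(seq_len(L))) {
    layer <- net$layers[[l]]
    cache <- caches[[l]]
    if (l == L && topIsPre) {
      dY <- d
    } else {
      dY <- switch(layer$act,
                   relu = d * (cache$preAct > 0),
                   sigmoid = d * cache$out * (1 - cache$out),
                   linear = d)
    }
    if (!is.null(layer$bn)) {
      xhat <- cache$xhat
      n <- nrow(xhat)
      dGamma <- colSums(dY * xhat)
      dBeta <- colSums(dY)
      dXhat <- sweep(dY, 2, layer$bn$gamma, "*")
      inv <- 1 / sqrt(cache$va + BN_EPS)
      if (evalMode) {
        dZ <- sweep(dXhat, 2, inv, "*")
      } else {
        dZ <- sweep(dXhat - matrix(colMeans(dXhat), n, ncol(xhat), byrow = TRUE) -
                      xhat * matrix(colMeans(dXhat * xhat), n, ncol(xhat),
                                    byrow = TRUE),
                    2, inv, "*")
      }
      grads[[l]] <- list(W = crossprod(cache$X, dZ), b = colSums(dZ),
                         gamma = dGamma, beta = dBeta)
    } else {
      dZ <- dY
      grads[[l]] <- list(W = crossprod(cache$X, dZ), b = colSums(dZ))
    }
    d <- dZ %*% t(layer$W)
  }
  list(grads = grads, dX = d)
}

## ---- Adam ------------------------------------------------------------

adamInitNet <- function(net) {
  lapply(net$layers, function(layer) {
    s <- list(W = list(m = layer$W * 0, v = layer$W * 0),
              b = list(m = layer$b * 0, v = layer$b * 0))
    if (!is.null(layer$bn))
      s <- c(s, list(gamma = list(m = layer$bn$gamma * 0, v = layer$bn$gamma * 0),
                     beta = list(m = layer$bn$beta * 0, v = layer$bn$beta * 0)))
    s
  })
}

adamApply <- function(param, grad, slot, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  slot$m <- beta1 * slot$m + (1 - beta1) * grad
  slot$v <- beta2 * slot$v + (1 - beta2) * grad^2
  mhat <- slot$m / (1 - beta1^t)
  vhat <- slot$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), slot = slot)
}

adamStepNet <- function(net, grads, state, lr, t) {
  for (l in seq_along(net$layers)) {
    u <- adamApply(net$layers[[l]]$W, grads[[l]]$W, state[[l]]$W, lr, t)
    net$layers[[l]]$W <- u$param; state[[l]]$W <- u$slot
    u <- adamApply(net$layers[[l]]$b, grads[[l]]$b, state[[l]]$b, lr, t)
    net$layers[[l]]$b <- u$param; state[[l]]$b <- u$slot
    if (!is.null(net$layers[[l]]$bn)) {
      u <- adamApply(net$layers[[l]]$bn$gamma, grads[[l]]$gamma,
                     state[[l]]$gamma, lr, t)
      net$layers[[l]]$bn$gamma <- u$param; state[[l]]$gamma <- u$slot
      u <- adamApply(net$layers[[l]]$bn$beta, grads[[l]]$beta,
                     state[[l]]$beta, lr, t)
      net$layers[[l]]$bn$beta <- u$param; state[[l]]$beta <- u$slot
    }
  }
  list(net = net, state = state)
}

mlpParamCount <- function(net) {
  sum(vapply(net$layers, function(layer) {
    n <- length(layer$W) + length(layer$b)
    if (!is.null(layer$bn)) n <- n + length(layer$bn$gamma) + length(layer$bn$beta)
    n
  }, numeric(1)))
}
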