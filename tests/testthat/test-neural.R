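test_that("autoencoder construction validates widths and counts parameters", {
  spec <- list(inputDim = 64, h1 = 32, h2 = 16, bottleneck = 8)
  ae <- buildAutoencoder(spec, seed = 3)
  # dense W+b plus 2 batch-norm parameters per normalized layer
  dense <- function(i, o, bn) i * o + o + if (bn) 2 * o else 0
  expected <- dense(64, 32, TRUE) + dense(32, 16, TRUE) + dense(16, 8, TRUE) +
    dense(8, 16, TRUE) + dense(16, 32, TRUE) + dense(32, 64, FALSE)
  expect_equal(aeParamCount(ae), expected)

  expect_error(buildAutoencoder(list(inputDim = 10, h1 = 12, h2 = 4,
                                     bottleneck = 2)), "widths")
  expect_error(buildAutoencoder(list(inputDim = 10, h1 = 8, h2 = 4,
                                     bottleneck = 0)), "widths")

  # seeded determinism of initialization
  ae2 <- buildAutoencoder(spec, seed = 3)
  expect_identical(ae, ae2)
  ae3 <- buildAutoencoder(spec, seed = 4)
  expect_false(identical(ae$encoder$layers[[1]]$W, ae3$encoder$layers[[1]]$W))

  # sigmoid output keeps reconstructions in (0,1)
  set.seed(1)
  X <- matrix(rbinom(10 * 64, 1, 0.3), 10, 64)
  rec <- aeForward(ae, X)$recon
  expect_true(all(rec > 0 & rec < 1))
})

test_that("backpropagation matches finite-difference gradients", {
  # small net with batch norm, ReLU and sigmoid output, checked end to end
  net <- driverSigDR:::mlpBuild(c(5, 4, 3), c("relu", "sigmoid"),
                                c(TRUE, FALSE), seed = 2)
  set.seed(7)
  X <- matrix(rnorm(8 * 5), 8, 5)
  Tg <- matrix(rbinom(8 * 3, 1, 0.5), 8, 3)
  lossOf <- function(net) {
    p <- driverSigDR:::mlpForward(net, X, training = TRUE)$out
    driverSigDR:::meanBCE(Tg, p)
  }
  fw <- driverSigDR:::mlpForward(net, X, training = TRUE)
  analytic <- driverSigDR:::mlpBackward(net, fw$caches,
                                        (fw$out - Tg) / length(Tg),
                                        topIsPre = TRUE)$grads
  eps <- 1e-6
  for (l in 1:2) {
    for (par in c("W", "b")) {
      ref <- if (par == "W") net$layers[[l]]$W else net$layers[[l]]$b
      idx <- seq_len(min(6, length(ref)))
      for (k in idx) {
        up <- net; down <- net
        if (par == "W") {
          up$layers[[l]]$W[k] <- up$layers[[l]]$W[k] + eps
          down$layers[[l]]$W[k] <- down$layers[[l]]$W[k] - eps
        } else {
          up$layers[[l]]$b[k] <- up$layers[[l]]$b[k] + eps
          down$layers[[l]]$b[k] <- down$layers[[l]]$b[k] - eps
        }
        num <- (lossOf(up) - lossOf(down)) / (2 * eps)
        expect_equal(analytic[[l]][[par]][k], num, tolerance = 1e-4)
      }
    }
  }
  # batch-norm scale/shift gradients
  for (par in c("gamma", "beta")) {
    for (k in 1:2) {
      up <- net; down <- net
      up$layers[[1]]$bn[[par]][k] <- up$layers[[1]]$bn[[par]][k] + eps
      down$layers[[1]]$bn[[par]][k] <- down$layers[[1]]$bn[[par]][k] - eps
      num <- (lossOf(up) - lossOf(down)) / (2 * eps)
      expect_equal(analytic[[1]][[par]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("unified loss equals a scalar-loop oracle and its closed forms", {
  set.seed(5)
  n <- 7
  s <- rnorm(n); sPred <- rnorm(n)
  Rc <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
  Rd <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  pC <- matrix(runif(n * 4, 0.05, 0.95), n, 4)
  pD <- matrix(runif(n * 6, 0.05, 0.95), n, 6)
  expect_equal(unifiedLoss(s, sPred, Rc, pC, Rd, pD, 1, 1),
               unifiedLossOracle(s, sPred, Rc, pC, Rd, pD, 1, 1),
               tolerance = 1e-10)
  expect_equal(unifiedLoss(s, sPred, Rc, pC, Rd, pD, 0.3, 2),
               unifiedLossOracle(s, sPred, Rc, pC, Rd, pD, 0.3, 2),
               tolerance = 1e-10)
  # a perfect prediction leaves only the reconstruction terms
  expect_equal(unifiedLoss(s, s, Rc, pC, Rd, pD),
               unifiedLossOracle(s, s, Rc, pC, Rd, pD, 1, 1), tolerance = 1e-10)
  # reconstruction probability 0.5 costs exactly ln 2 per bit
  half <- matrix(0.5, n, 4); halfD <- matrix(0.5, n, 6)
  expect_equal(unifiedLoss(s, s, Rc, half, Rd, halfD), 2 * log(2),
               tolerance = 1e-12)
  expect_error(unifiedLoss(s, s, Rc, half * 2.2, Rd, halfD), "inside")
})

test_that("an autoencoder can memorize a small binary set", {
  set.seed(21)
  X <- matrix(rbinom(50 * 64, 1, 0.3), 50, 64)
  ae <- buildAutoencoder(list(inputDim = 64, h1 = 32, h2 = 16, bottleneck = 8),
                         seed = 21)
  fit <- trainAutoencoder(ae, X, epochs = 400, batchSize = 50, lr = 1e-2,
                          seed = 21)
  expect_lt(tail(fit$history$trainBCE, 1), 0.05)
  expect_error(trainAutoencoder(ae, X + 0.5), "binary")
})

test_that("width grid search selects by held-out BCE with degenerate grids", {
  set.seed(4)
  X <- matrix(rbinom(60 * 32, 1, 0.25), 60, 32)
  res <- pretrainAutoencoder(X, grid = list(h1 = 16, h2 = 8, bottleneck = 4),
                             epochs = 5, seed = 2)
  expect_equal(res$spec, list(inputDim = 32, h1 = 16, h2 = 8, bottleneck = 4))
  expect_equal(nrow(res$table), 1L)

  res2 <- pretrainAutoencoder(X, grid = list(h1 = 16, h2 = c(8, 4),
                                             bottleneck = 4),
                              epochs = 5, seed = 2)
  expect_equal(nrow(res2$table), 2L)
  expect_equal(min(res2$table$heldOutBCE),
               res2$table$heldOutBCE[which(res2$table$h2 == res2$spec$h2)])
})

test_that("model forward obeys the concatenation contract", {
  model <- buildModel(paste0("p", 1:5),
                      mutSpec = list(inputDim = 12, h1 = 8, h2 = 6, bottleneck = 3),
                      drugSpec = list(inputDim = 20, h1 = 10, h2 = 6, bottleneck = 4),
                      seed = 9)
  # predictor input width = pathways + both bottlenecks
  expect_equal(model@fnn$dims[1], 5 + 3 + 4)
  set.seed(2)
  n <- 6
  A <- matrix(rnorm(n * 5), n, 5)
  Rc <- matrix(rbinom(n * 12, 1, 0.3), n, 12)
  Rd <- matrix(rbinom(n * 20, 1, 0.1), n, 20)
  out <- modelForward(model, A, Rc, Rd)
  expect_length(out$sPred, n)
  expect_true(all(out$rcRecon > 0 & out$rcRecon < 1))
  expect_true(all(out$rdRecon > 0 & out$rdRecon < 1))

  # batching preserves order
  out2 <- modelForward(model, A[c(3, 1), ], Rc[c(3, 1), ], Rd[c(3, 1), ])
  expect_equal(out2$sPred, out$sPred[c(3, 1)], tolerance = 1e-12)

  # a zeroed predictor returns its output bias everywhere
  zero <- model
  for (l in seq_along(zero@fnn$layers)) {
    zero@fnn$layers[[l]]$W[] <- 0
    if (!is.null(zero@fnn$layers[[l]]$bn)) zero@fnn$layers[[l]]$bn$beta[] <- 0
  }
  zero@fnn$layers[[3]]$b <- 0.75
  expect_equal(unname(modelForward(zero, A, Rc, Rd)$sPred), rep(0.75, n))

  expect_error(modelForward(model, A, Rd, Rc), "mutation block")
  expect_error(modelForward(model, A[, 1:3], Rc, Rd), "activity block")
})

test_that("end-to-end training stops early and returns the best state", {
  co <- smallTestCohort()
  sets <- co@geneSets[sprintf("pathway_%02d", 1:4)]
  act <- activityMatrix(co@expression, sets)
  features <- list(activity = act, mutations = co@mutations,
                   fingerprints = co@fingerprints)
  sp <- splitPairs(co@pairs, "mix", seed = 4)
  model <- buildModel(rownames(act),
                      mutSpec = list(inputDim = nrow(co@mutations), h1 = 12,
                                     h2 = 6, bottleneck = 4),
                      drugSpec = list(inputDim = 128, h1 = 32, h2 = 12,
                                      bottleneck = 6), seed = 5)
  cfg <- list(lr = 1e-3, batchSize = 64L, maxEpochs = 25L, patience = 3L,
              seed = 5)
  fit <- trainEndToEnd(model, sp$train, sp$val, features, cfg)
  h <- trainingHistory(fit)
  expect_gt(nrow(h), 1)
  # stopping rule: no more than patience epochs after the best one
  expect_lte(nrow(h), which.min(h$valLoss) + cfg$patience)
  # returned state reproduces the best validation loss
  vb <- driverSigDR:::pairBatch(sp$val, features)
  expect_equal(driverSigDR:::evalLoss(fit, vb, 1, 1), min(h$valLoss),
               tolerance = 1e-9)

  # determinism: identical config and seed give identical histories
  fit2 <- trainEndToEnd(model, sp$train, sp$val, features, cfg)
  expect_identical(trainingHistory(fit2), h)

  # overlapping train/val is rejected
  expect_error(trainEndToEnd(model, sp$train, sp$train[1, ], features, cfg),
               "overlap")

  # checkpoint round trip reproduces predictions bitwise
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(fit, f)
  back <- loadModel(f)
  tb <- driverSigDR:::pairBatch(sp$test, features)
  expect_identical(modelForward(back, tb$A, tb$Rc, tb$Rd)$sPred,
                   modelForward(fit, tb$A, tb$Rc, tb$Rd)$sPred)

  # prediction plumbing: order equivariance, duplicates, rejects report
  pr <- sp$test[1:5, ]
  p1 <- predictPairs(fit, features, pr)
  p2 <- predictPairs(fit, features, pr[5:1, ])
  expect_equal(as.numeric(p2), rev(as.numeric(p1)), tolerance = 1e-12)
  dup <- predictPairs(fit, features, pr[c(1, 1), ])
  expect_equal(dup[[1]], dup[[2]])
  odd <- rbind(pr, data.frame(cellId = "noSuchCell", drugId = pr$drugId[1],
                              lnIC50 = 0, source = "synthetic"))
  po <- predictPairs(fit, features, odd)
  expect_equal(nrow(attr(po, "rejects")), 1L)
  expect_match(attr(po, "rejects")$reason, "cell")
})
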