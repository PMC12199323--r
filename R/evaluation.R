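#' Partition cell-drug pairs for training, validation and testing
#'
#' Four strategies: `"mix"` partitions pairs at random; `"cell"` partitions
#' cells and sends every pair with its cell (no cell appears in two
#' partitions); `"drug"` is symmetric for drugs; `"both"` independently
#' partitions cells and drugs, keeps a pair only if its cell and drug fall
#' in the same partition, and discards cross-partition pairs (count
#' reported). Partition sizes use deterministic largest-remainder rounding.
#'
#' @param pairs data.frame with `cellId`, `drugId` (and typically `lnIC50`).
#' @param strategy one of "mix", "cell", "drug", "both".
#' @param fractions train/validation/test fractions, positive, summing to 1;
#'   default c(0.8, 0.1, 0.1).
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` data.frames, `nDiscarded`
#'   (0 except for "both"), and `assignments` (the entity -> partition
#'   labels for the entity-based strategies; NULL for "mix").
#' @export
splitPairs <- function(pairs, strategy = c("mix", "cell", "drug", "both"),
                       fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  strategy <- match.arg(strategy)
  stopIfNot(length(fractions) == 3 && all(fractions > 0) &&
              abs(sum(fractions) - 1) < 1e-8,
            "fractions must be 3 positive numbers summing to 1")
  stopIfNot(nrow(pairs) >= 3, "too few pairs to split")
  assign3 <- function(ids) {
    sizes <- largestRemainder(length(ids), fractions)
    lab <- rep(c("train", "val", "test"), times = sizes)
    stats::setNames(sample(lab), ids)   # random assignment, fixed sizes
  }
  res <- withSeed(substreamSeed(seed, paste0("split-", strategy)), {
    if (strategy == "mix") {
      lab <- assign3(seq_len(nrow(pairs)))
      list(part = unname(lab), nDiscarded = 0L, assignments = NULL)
    } else if (strategy %in% c("cell", "drug")) {
      idCol <- if (strategy == "cell") pairs$cellId else pairs$drugId
      ids <- unique(idCol)
      stopIfNot(length(ids) >= 3,
                paste("need >= 3 distinct", strategy, "entities"))
      lab <- assign3(ids)
      list(part = unname(lab[idCol]), nDiscarded = 0L,
           assignments = stats::setNames(list(lab), strategy))
    } else {
      cells <- unique(pairs$cellId); drugs <- unique(pairs$drugId)
      stopIfNot(length(cells) >= 3 && length(drugs) >= 3,
                "need >= 3 distinct cells and drugs")
      labC <- assign3(cells); labD <- assign3(drugs)
      pc <- unname(labC[pairs$cellId]); pd <- unname(labD[pairs$drugId])
      part <- ifelse(pc == pd, pc, NA_character_)
      list(part = part, nDiscarded = sum(is.na(part)),
           assignments = list(cell = labC, drug = labD))
    }
  })
  part <- res$part
  out <- list(train = pairs[!is.na(part) & part == "train", , drop = FALSE],
              val = pairs[!is.na(part) & part == "val", , drop = FALSE],
              test = pairs[!is.na(part) & part == "test", , drop = FALSE],
              nDiscarded = res$nDiscarded,
              assignments = res$assignments)
  empty <- names(which(vapply(out[1:3], nrow, integer(1)) == 0))
  if (length(empty))
    stop("empty partition(s): ", paste(empty, collapse = ", "),
         "; use more data or different fractions", call. = FALSE)
  rownames(out$train) <- rownames(out$val) <- rownames(out$test) <- NULL
  out
}

#' Regression metrics: Pearson correlation and RMSE
#'
#' @param pred,obs equal-length numeric vectors (n >= 2).
#' @return list with `pcc` (NA when `obs` is constant) and `rmse`.
#' @export
regressionMetrics <- function(pred, obs) {
  stopIfNot(length(pred) == length(obs) && length(obs) >= 2,
            "need equal-length vectors with n >= 2")
  pcc <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) NA_real_
         else stats::cor(pred, obs)
  list(pcc = pcc, rmse = sqrt(mean((pred - obs)^2)))
}

## rank-based AUROC with higher score = positive class
aurocFromScores <- function(score, label) {
  if (length(unique(label)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = label, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' Sensitive/insensitive classification by the observed lowest quartile
#'
#' The threshold tau is the 25th percentile (linear interpolation between
#' order statistics) of the observed LN IC50; observations and predictions
#' at or below tau are labeled sensitive (the positive class, since lower
#' IC50 means greater sensitivity). F1 is computed from the binary labels;
#' AUROC ranks observed labels by -prediction so that higher score means
#' more sensitive.
#'
#' @param pred,obs numeric vectors, n >= 4; `obs` must not be constant.
#' @param sensitiveLow if FALSE, flips the convention to label the highest
#'   quartile; default TRUE.
#' @return list: `tau`, `labelsObs`, `labelsPred` (logical, TRUE =
#'   sensitive), `auroc`, `f1`.
#' @export
quartileClassification <- function(pred, obs, sensitiveLow = TRUE) {
  stopIfNot(length(pred) == length(obs) && length(obs) >= 4,
            "need equal-length vectors with n >= 4")
  if (max(obs) == min(obs))
    stop("observed values are all identical: quartile undefined", call. = FALSE)
  if (sensitiveLow) {
    tau <- unname(stats::quantile(obs, 0.25, type = 7))
    labObs <- obs <= tau
    labPred <- pred <= tau
    score <- -pred
  } else {
    tau <- unname(stats::quantile(obs, 0.75, type = 7))
    labObs <- obs >= tau
    labPred <- pred >= tau
    score <- pred
  }
  tp <- sum(labPred & labObs)
  prec <- if (sum(labPred) == 0) NA_real_ else tp / sum(labPred)
  rec <- if (sum(labObs) == 0) NA_real_ else tp / sum(labObs)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) 0
        else 2 * prec * rec / (prec + rec)
  list(tau = tau, labelsObs = labObs, labelsPred = labPred,
       auroc = aurocFromScores(score, labObs), f1 = f1)
}

#' Per-cell or per-drug metric reports
#'
#' Computes PCC/RMSE/AUROC/F1 within each entity's pairs; entities with
#' fewer than 3 pairs or constant observations are skipped and counted.
#'
#' @param pairs data.frame with `cellId`, `drugId`, `lnIC50`.
#' @param pred predictions aligned to `pairs` rows.
#' @param by "cell" or "drug".
#' @return list: `reports` (one row per retained entity), `summary`
#'   (mean/sd per metric), `nSkipped`.
#' @export
perEntityMetrics <- function(pairs, pred, by = c("cell", "drug")) {
  by <- match.arg(by)
  ids <- if (by == "cell") pairs$cellId else pairs$drugId
  rows <- list(); nSkipped <- 0L
  for (id in unique(ids)) {
    sel <- ids == id
    o <- pairs$lnIC50[sel]; p <- pred[sel]
    if (sum(sel) < 3 || max(o) == min(o)) { nSkipped <- nSkipped + 1L; next }
    rm <- regressionMetrics(p, o)
    qc <- if (sum(sel) >= 4) tryCatch(quartileClassification(p, o),
                                      error = function(e) NULL) else NULL
    rows[[id]] <- data.frame(entity = id, n = sum(sel), pcc = rm$pcc,
                             rmse = rm$rmse,
                             auroc = if (is.null(qc)) NA_real_ else qc$auroc,
                             f1 = if (is.null(qc)) NA_real_ else qc$f1)
  }
  if (length(rows) == 0) stop("no entity with enough pairs", call. = FALSE)
  reports <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  mets <- c("pcc", "rmse", "auroc", "f1")
  summary <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(reports[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(mets, function(m) stats::sd(reports[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  list(reports = reports, summary = summary, nSkipped = nSkipped)
}

#' Monte Carlo cross-validation of the full model
#'
#' Repeats (fresh 8:1:1 mix split -> end-to-end training -> test metrics)
#' `nIter` times with iteration seeds derived from the master seed.
#'
#' @param pairs full pair table.
#' @param features feature list (see [trainEndToEnd()]).
#' @param modelBuilder function(seed) returning an untrained
#'   [DeepSensModel-class] (width specs fixed by the caller).
#' @param config training config (see [trainEndToEnd()]).
#' @param nIter number of iterations; default 10.
#' @param seed master seed.
#' @return list: `reports` (data.frame, one row per iteration: pcc, rmse,
#'   auroc, f1, n), `summary` (mean/sd per metric).
#' @export
monteCarloCV <- function(pairs, features, modelBuilder, config = list(),
                         nIter = 10L, seed = 1L) {
  stopIfNot(nIter >= 1, "nIter must be >= 1")
  rows <- vector("list", nIter)
  for (i in seq_len(nIter)) {
    iterSeed <- substreamSeed(seed, paste0("mccv", i))
    res <- tryCatch({
      sp <- splitPairs(pairs, "mix", seed = iterSeed)
      model <- modelBuilder(iterSeed)
      cfg <- utils::modifyList(config, list(seed = iterSeed))
      fit <- trainEndToEnd(model, sp$train, sp$val, features, cfg)
      tbt <- pairBatch(sp$test, features)
      predT <- modelForward(fit, tbt$A, tbt$Rc, tbt$Rd)$sPred
      rm <- regressionMetrics(predT, tbt$s)
      qc <- quartileClassification(predT, tbt$s)
      data.frame(iteration = i, n = nrow(sp$test), pcc = rm$pcc,
                 rmse = rm$rmse, auroc = qc$auroc, f1 = qc$f1)
    }, error = function(e)
      stop("Monte Carlo iteration ", i, " (seed ", iterSeed, ") failed: ",
           conditionMessage(e), call. = FALSE))
    rows[[i]] <- res
  }
  reports <- do.call(rbind, rows)
  mets <- c("pcc", "rmse", "auroc", "f1")
  list(reports = reports,
       summary = data.frame(
         metric = mets,
         mean = vapply(mets, function(m) mean(reports[[m]]), numeric(1)),
         sd = vapply(mets, function(m) stats::sd(reports[[m]]), numeric(1)),
         row.names = NULL))
}
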