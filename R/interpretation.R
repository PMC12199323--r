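## gradient of a network's scalar output w.r.t. its input rows, in
## evaluation mode (batch-norm uses running statistics, so the map is
## differentiable sample-by-sample)
netInputGradient <- function(net, X) {
  ff <- mlpForward(net, X, training = FALSE)
  mlpBackward(net, ff$caches, matrix(1, nrow(X), 1), topIsPre = TRUE,
              evalMode = TRUE)$dX
}

igOnNet <- function(net, X, baseline, steps) {
  n <- nrow(X); d <- ncol(X)
  # all samples x all interpolation points in one forward/backward batch
  alphas <- seq_len(steps) / steps           # right-Riemann rule
  Xrep <- X[rep(seq_len(n), each = steps), , drop = FALSE]
  Brep <- matrix(baseline, n * steps, d, byrow = TRUE)
  pts <- Brep + alphas * (Xrep - Brep)       # alphas recycles over rows
  grads <- netInputGradient(net, pts)
  if (any(!is.finite(grads))) {
    badSample <- unique((which(!is.finite(grads), arr.ind = TRUE)[, 1] - 1) %/%
                          steps + 1)
    stop("non-finite gradient for sample(s): ",
         paste(badSample, collapse = ", "), call. = FALSE)
  }
  avg <- matrix(0, n, d)
  for (k in seq_len(steps))
    avg <- avg + grads[seq(k, n * steps, by = steps), , drop = FALSE]
  avg <- avg / steps
  sweep(X, 2, baseline, "-") * avg
}

#' Assemble the predictor-input matrix for a set of pairs
#'
#' Runs the two encoders in evaluation mode and concatenates pathway
#' activities with the mutation and drug bottleneck embeddings — the
#' feature space over which attributions are computed.
#'
#' @param model a trained [DeepSensModel-class].
#' @param A,Rc,Rd per-pair feature blocks (samples in rows).
#' @return samples x (pathways + bottleneckC + bottleneckD) matrix with
#'   feature column names.
#' @export
predictorInputs <- function(model, A, Rc, Rd) {
  out <- modelForward(model, A, Rc, Rd)
  X <- cbind(A, out$zC, out$zD)
  colnames(X) <- c(model@signaturePathways,
                   paste0("mut_dim", seq_len(ncol(out$zC))),
                   paste0("drug_dim", seq_len(ncol(out$zD))))
  X
}

#' Integrated-gradients attribution over the predictor input
#'
#' For each sample x and feature i, IG_i = (x_i - x'_i) times the average
#' gradient of the predictor output along the straight path from the
#' baseline x' to x (right-Riemann approximation with `steps` points).
#' Attributions are taken with respect to the predictor's input layer
#' (pathway activities and the two bottleneck embeddings); they are not
#' propagated back through the encoders. For an affine predictor the result
#' is exact at any step count, and in general the completeness axiom
#' sum_i IG_i = F(x) - F(x') holds as steps grow.
#'
#' @param model a trained [DeepSensModel-class].
#' @param inputs predictor-input matrix from [predictorInputs()].
#' @param baseline baseline vector (length = ncol(inputs)); default zeros.
#' @param steps path resolution; default 50.
#' @return samples x features attribution matrix.
#' @export
integratedGradients <- function(model, inputs, baseline = NULL, steps = 50L) {
  stopIfNot(steps >= 1, "steps must be >= 1")
  d <- ncol(inputs)
  baseline <- baseline %||% numeric(d)
  stopIfNot(length(baseline) == d, "baseline length must match input width")
  attr <- igOnNet(model@fnn, as.matrix(inputs), baseline, steps)
  dimnames(attr) <- dimnames(inputs)
  attr
}

#' Global IG scores: per-feature attribution averaged over samples
#'
#' Negative scores mean the feature pushes predicted LN IC50 down
#' (increases predicted sensitivity); positive scores the opposite.
#' Features are conventionally ranked by absolute score.
#'
#' @param attributions matrix from [integratedGradients()].
#' @return named numeric vector of column means.
#' @export
globalIG <- function(attributions) {
  stopIfNot(nrow(attributions) >= 1, "need >= 1 sample")
  colMeans(attributions)
}

#' Write global IG scores as a ranked TSV
#'
#' @param scores vector from [globalIG()]
#' @param path output file
#' @export
writeIGScores <- function(scores, path) {
  ord <- order(abs(scores), decreasing = TRUE)
  utils::write.table(
    data.frame(feature = names(scores)[ord], score = unname(scores[ord]),
               absRank = seq_along(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pathway annotation of embedding dimensions by correlation GSEA
#'
#' Correlates each embedding dimension (row of E) with every gene's
#' expression (rows of G) across shared samples, ranks genes by descending
#' correlation, runs preranked GSEA per dimension, and retains pathways
#' with FDR below the cutoff. Constant dimensions are skipped (reported);
#' constant gene rows are dropped from the correlation universe.
#'
#' @param E dimension x sample embedding matrix.
#' @param G gene x sample expression matrix (same sample columns).
#' @param collection named list of gene sets.
#' @param fdrMax annotation cutoff; default 0.01.
#' @param nPerm,seed permutation-null settings passed to [gsea()].
#' @param exponent GSEA weighting exponent; default 1.
#' @return list: `annotations` (per-dimension data.frame of surviving
#'   pathways with es/fdr/correlation sign, empty rows for unannotated
#'   dimensions), `skippedDims` (constant dimensions), `droppedGenes`.
#' @export
annotateDimensions <- function(E, G, collection, fdrMax = 0.01,
                               nPerm = 1000L, seed = 1L, exponent = 1) {
  stopIfNot(ncol(E) == ncol(G) && ncol(E) >= 3,
            "E and G need >= 3 shared sample columns")
  if (!is.null(colnames(E)) && !is.null(colnames(G)))
    stopIfNot(identical(colnames(E), colnames(G)),
              "sample columns of E and G must match")
  constGene <- apply(G, 1, function(r) max(r) == min(r))
  G2 <- G[!constGene, , drop = FALSE]
  stopIfNot(nrow(G2) >= 2, "fewer than 2 non-constant gene rows")
  dimNames <- rownames(E) %||% paste0("dim", seq_len(nrow(E)))
  skipped <- character()
  annotations <- stats::setNames(vector("list", nrow(E)), dimNames)
  for (i in seq_len(nrow(E))) {
    e <- as.numeric(E[i, ])
    if (max(e) == min(e)) {
      skipped <- c(skipped, dimNames[i])
      next
    }
    cc <- as.numeric(stats::cor(e, t(G2)))
    names(cc) <- rownames(G2)
    rec <- suppressWarnings(
      gsea(rankedList(cc), collection, exponent = exponent, nPerm = nPerm,
           seed = substreamSeed(seed, paste0("annot", i))))
    keep <- rec$fdr < fdrMax
    annotations[[dimNames[i]]] <- data.frame(
      pathway = rec$pathway[keep], es = rec$es[keep], fdr = rec$fdr[keep],
      correlationSign = ifelse(rec$es[keep] > 0, "positive", "negative"),
      row.names = NULL)
  }
  for (nm in names(annotations))
    if (is.null(annotations[[nm]]) && !(nm %in% skipped))
      annotations[[nm]] <- data.frame(pathway = character(), es = numeric(),
                                      fdr = numeric(),
                                      correlationSign = character())
  list(annotations = annotations[setdiff(dimNames, skipped)],
       skippedDims = skipped,
       droppedGenes = rownames(G)[constGene] %||% character())
}

#' Group cells as sensitive/insensitive by mean response quartile
#'
#' Each cell's mean LN IC50 across its drugs is computed; cells at or below
#' the 25th percentile of these means (linear-interpolation percentile) are
#' labeled sensitive.
#'
#' @param pairs data.frame with `cellId`, `lnIC50`.
#' @return named character vector cell -> "sensitive"/"insensitive".
#' @export
groupCellsBySensitivity <- function(pairs) {
  means <- vapply(split(pairs$lnIC50, pairs$cellId), mean, numeric(1))
  stopIfNot(length(means) >= 4, "need >= 4 cells")
  if (max(means) == min(means))
    stop("all cell means identical: quartile undefined", call. = FALSE)
  tau <- unname(stats::quantile(means, 0.25, type = 7))
  stats::setNames(ifelse(means <= tau, "sensitive", "insensitive"),
                  names(means))
}
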