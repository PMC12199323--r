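#' Single-sample GSEA activity of one gene set in one sample
#'
#' Genes are ranked in descending order of expression within the sample; the
#' gene at position i carries rank value N - i + 1. The statistic is the sum
#' over all list positions of the difference between the weighted hit ECDF
#' (hit weights rank^alpha, normalized over the set's hits) and the
#' unweighted miss ECDF — the rank-weighted ssGSEA statistic of Barbie-style
#' pathway scoring.
#'
#' Ties in expression are broken by input order (stable sort); a constant
#' expression column is rejected because its ranking is arbitrary.
#'
#' @param expr named numeric vector: one sample's expression over genes.
#' @param geneSet character vector; must intersect `names(expr)` and not
#'   cover all genes.
#' @param alpha rank-weighting exponent; default 0.25.
#' @return scalar activity score.
#' @export
ssgseaSample <- function(expr, geneSet, alpha = 0.25) {
  stopIfNot(length(expr) >= 2, "need at least 2 genes")
  stopIfNot(!is.null(names(expr)) && !anyDuplicated(names(expr)),
            "expr must be named with unique genes")
  stopIfNot(all(is.finite(expr)), "expression must be finite")
  if (max(expr) == min(expr))
    stop("constant expression column: ranking undefined", call. = FALSE)
  N <- length(expr)
  ord <- order(-as.numeric(expr))          # stable: ties keep input order
  genes <- names(expr)[ord]
  hit <- genes %in% geneSet
  m <- sum(hit)
  if (m == 0) stop("gene set does not intersect expressed genes", call. = FALSE)
  if (m == N)
    stop("gene set covers all genes: miss distribution undefined", call. = FALSE)
  rankValue <- (N:1)^alpha                 # position 1 = highest expression
  w <- ifelse(hit, rankValue, 0)
  pHit <- cumsum(w) / sum(w)
  pMiss <- cumsum(!hit) / (N - m)
  sum(pHit - pMiss)
}

#' Pathway activity matrix by per-sample ssGSEA
#'
#' Applies [ssgseaSample()] to every (signature pathway, sample) pair.
#' Row order follows the signature, column order the expression matrix.
#'
#' @param expression gene x sample numeric matrix with dimnames.
#' @param signature a [PathwaySignature-class], or a named list of gene sets.
#' @param alpha rank-weighting exponent; default 0.25.
#' @param normalize if TRUE, linearly rescale the whole matrix by the range
#'   of scores (a cross-sample min-max normalization some pipelines apply);
#'   default FALSE (raw scores).
#' @param geneSets named list of gene sets giving each pathway's members;
#'   required when `signature` is a `PathwaySignature` (its table stores
#'   names, not members).
#' @return pathway x sample numeric matrix.
#' @export
activityMatrix <- function(expression, signature, geneSets = NULL,
                           alpha = 0.25, normalize = FALSE) {
  stopIfNot(is.matrix(expression) && ncol(expression) >= 1,
            "expression must be a matrix with >= 1 sample")
  stopIfNot(!is.null(rownames(expression)) && !is.null(colnames(expression)),
            "expression needs gene rownames and sample colnames")
  if (methods::is(signature, "PathwaySignature")) {
    stopIfNot(!is.null(geneSets), "geneSets required with a PathwaySignature")
    pw <- signaturePathways(signature)
    stopIfNot(all(pw %in% names(geneSets)),
              "signature pathways missing from geneSets")
    sets <- geneSets[pw]
  } else {
    stopIfNot(is.list(signature) && !is.null(names(signature)),
              "signature must be a PathwaySignature or a named list")
    sets <- signature
  }
  for (nm in names(sets))
    if (!any(sets[[nm]] %in% rownames(expression)))
      stop("pathway has no expressed member genes: ", nm, call. = FALSE)
  act <- vapply(seq_len(ncol(expression)), function(j) {
    col <- expression[, j]
    names(col) <- rownames(expression)
    vapply(sets, function(s) ssgseaSample(col, s, alpha), numeric(1))
  }, numeric(length(sets)))
  act <- matrix(act, nrow = length(sets),
                dimnames = list(names(sets), colnames(expression)))
  if (normalize) act <- act / (max(act) - min(act))
  act
}

#' Write a pathway x sample activity matrix as TSV
#'
#' @param act matrix from [activityMatrix()]
#' @param path output file
#' @export
writeActivityMatrix <- function(act, path) {
  utils::write.table(data.frame(pathway = rownames(act), act,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
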