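#' Build a ranked gene list from a named score vector
#'
#' Sorts genes by descending score with ties broken by input order (stable
#' sort), producing the non-increasing ranked list consumed by [gsea()].
#'
#' @param scores named numeric vector (e.g. propagation scores).
#' @return named numeric vector, non-increasing.
#' @export
rankedList <- function(scores) {
  stopIfNot(!is.null(names(scores)) && all(nzchar(names(scores))),
            "scores must be named")
  stopIfNot(!anyDuplicated(names(scores)), "duplicate gene identifiers")
  stopIfNot(all(is.finite(scores)), "scores must be finite")
  ord <- order(-as.numeric(scores))  # radix order is stable
  scores[ord]
}

checkRanked <- function(ranked) {
  stopIfNot(is.numeric(ranked) && !is.null(names(ranked)),
            "ranked list must be a named numeric vector")
  stopIfNot(!anyDuplicated(names(ranked)), "duplicate genes in ranked list")
  stopIfNot(!is.unsorted(rev(ranked)), "ranked list must be non-increasing")
}

#' Weighted Kolmogorov-Smirnov enrichment score with leading edge
#'
#' Walks the ranked list accumulating |weight|^exponent / sum(|weight|^exponent)
#' at gene-set hits and -1/(N - nHits) at misses; the enrichment score is the
#' signed maximum deviation of this running sum from zero. The leading edge
#' contains the set members at or before the peak for positive scores, and at
#' or after the peak for negative scores.
#'
#' @param ranked named numeric vector, non-increasing (see [rankedList()]).
#' @param geneSet character vector of member genes; must intersect `ranked`.
#' @param exponent weighting exponent >= 0; 0 gives the classic unweighted
#'   statistic, 1 (default) the standard weighted one.
#' @return list with `es`, `leadingEdge`, `peak` (peak position).
#' @export
enrichmentScore <- function(ranked, geneSet, exponent = 1) {
  checkRanked(ranked)
  stopIfNot(exponent >= 0, "exponent must be >= 0")
  genes <- names(ranked)
  N <- length(genes)
  hit <- genes %in% geneSet
  m <- sum(hit)
  if (m == 0) stop("gene set does not intersect the ranked list", call. = FALSE)
  if (m == N) stop("gene set covers the whole ranked list", call. = FALSE)
  w <- abs(as.numeric(ranked))^exponent
  nr <- sum(w[hit])
  if (nr == 0)
    stop("all hit weights are zero at exponent > 0", call. = FALSE)
  step <- ifelse(hit, w / nr, -1 / (N - m))
  running <- cumsum(step)
  peak <- which.max(abs(running))
  es <- running[peak]
  le <- if (es >= 0) genes[hit & seq_len(N) <= peak]
        else genes[hit & seq_len(N) >= peak]
  list(es = unname(es), leadingEdge = le, peak = peak)
}

## Vectorized ES over a matrix of hit positions (one permutation per row,
## rows sorted ascending). wPow = |weight|^exponent along the ranked list.
## The running sum attains its extrema immediately after a hit (maximum
## candidates) or immediately before one (minimum candidates), so only 2m
## values per permutation need evaluating.
esFromPositions <- function(pos, wPow, N) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
  m <- ncol(pos)
  W <- matrix(wPow[pos], nrow = nrow(pos))
  nr <- rowSums(W)
  cw <- W
  if (m > 1) for (k in 2:m) cw[, k] <- cw[, k - 1] + cw[, k]
  cw <- cw / nr
  K <- matrix(rep(seq_len(m), each = nrow(pos)), nrow = nrow(pos))
  D <- (pos - K) / (N - m)          # misses accumulated up to each hit
  afterHit <- cw - D
  beforeHit <- cbind(0, cw[, -m, drop = FALSE]) - D
  hi <- do.call(pmax, as.data.frame(afterHit))
  lo <- do.call(pmin, as.data.frame(beforeHit))
  ifelse(hi >= -lo, hi, lo)
}

#' Preranked GSEA over a gene-set collection with a permutation null
#'
#' Computes the enrichment score of every set against the ranked list, then
#' an empirical p-value from a null of size-matched random gene sets drawn
#' from the ranked universe. As in classic GSEA, the comparison is
#' restricted to same-signed null scores:
#' p = (1 + #(null >= observed)) / (1 + #(null >= 0)) for a nonnegative
#' observed score, mirrored for a negative one — this keeps the p-value
#' uniformly distributed under the null (comparing against the full
#' two-signed null would double the type-I rate, since an instance lands
#' in either tail). FDR is Benjamini-Hochberg across the collection.
#'
#' @param ranked named non-increasing numeric vector ([rankedList()]).
#' @param collection named list of gene sets; sets that do not intersect the
#'   ranked universe are dropped with a warning.
#' @param exponent weighting exponent (default 1).
#' @param nPerm number of null draws per set (default 1000; must be >= 1).
#' @param seed integer seed making the null reproducible.
#' @return data.frame (pathway, size, es, pValue, fdr) in collection order,
#'   with the per-set leading edges in `attr(, "leadingEdges")`.
#' @export
gsea <- function(ranked, collection, exponent = 1, nPerm = 1000L, seed = 1L) {
  checkRanked(ranked)
  stopIfNot(length(collection) > 0 && !is.null(names(collection)),
            "collection must be a non-empty named list")
  stopIfNot(nPerm >= 1, "nPerm must be >= 1")
  genes <- names(ranked)
  N <- length(genes)
  wPow <- abs(as.numeric(ranked))^exponent
  sizes <- vapply(collection, function(s) sum(genes %in% s), integer(1))
  usable <- sizes >= 1 & sizes < N
  if (!any(usable)) stop("no usable gene set in the collection", call. = FALSE)
  if (!all(usable))
    warning(sum(!usable), " set(s) dropped (no overlap or full overlap)")
  collection <- collection[usable]
  sizes <- sizes[usable]
  obs <- lapply(collection, function(s) enrichmentScore(ranked, s, exponent))
  esObs <- vapply(obs, `[[`, numeric(1), "es")
  pv <- withSeed(seed, {
    vapply(seq_along(collection), function(k) {
      m <- sizes[k]
      pos <- t(vapply(seq_len(nPerm),
                      function(i) sort(sample.int(N, m)), integer(m)))
      null <- esFromPositions(pos, wPow, N)
      if (esObs[k] >= 0) (1 + sum(null >= esObs[k])) / (1 + sum(null >= 0))
      else (1 + sum(null <= esObs[k])) / (1 + sum(null < 0))
    }, numeric(1))
  })
  res <- data.frame(pathway = names(collection), size = sizes, es = esObs,
                    pValue = pv, fdr = stats::p.adjust(pv, method = "BH"),
                    row.names = NULL)
  attr(res, "leadingEdges") <- stats::setNames(
    lapply(obs, `[[`, "leadingEdge"), names(collection))
  res
}

#' Select the pathway signature from enrichment records
#'
#' Retains pathways with es > `esMin` and fdr < `fdrMax` (both strict),
#' ordered by ascending FDR then descending ES.
#'
#' @param records data.frame from [gsea()] (columns pathway, es, pValue,
#'   fdr; optionally a `leadingEdges` attribute).
#' @param esMin,fdrMax selection thresholds; defaults 0 and 0.2.
#' @return a [PathwaySignature-class].
#' @export
selectSignature <- function(records, esMin = 0, fdrMax = 0.2) {
  stopIfNot(is.data.frame(records) && nrow(records) > 0,
            "records must be a non-empty data.frame")
  keep <- records$es > esMin & records$fdr < fdrMax
  if (!any(keep))
    stop("no pathway passes es > ", esMin, " and fdr < ", fdrMax,
         "; consider relaxing the thresholds", call. = FALSE)
  tb <- records[keep, , drop = FALSE]
  tb <- tb[order(tb$fdr, -tb$es), , drop = FALSE]
  rownames(tb) <- NULL
  le <- attr(records, "leadingEdges") %||% list()
  methods::new("PathwaySignature", table = tb,
               leadingEdges = le[intersect(tb$pathway, names(le))],
               esMin = esMin, fdrMax = fdrMax)
}
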