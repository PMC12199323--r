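#' Build a high-confidence PPI network from multi-source edge records
#'
#' Each record is one observation of an interacting gene pair under one
#' source database. An undirected edge is kept iff the unordered pair is
#' supported by at least `minSources` *distinct* sources. Self-pairs are
#' discarded and duplicate records collapse.
#'
#' @param edgeRecords data.frame with columns `geneA`, `geneB`, `source`
#'   (one row per pair-source observation). Whitespace around identifiers is
#'   stripped; matching is exact string equality.
#' @param minSources minimum number of distinct supporting sources (>= 1);
#'   default 2.
#' @return a [PPINetwork-class] over all genes incident to a kept edge,
#'   nodes ordered by first appearance in the input.
#' @examples
#' edges <- data.frame(geneA = c("A", "A", "B"), geneB = c("B", "B", "C"),
#'                     source = c("s1", "s2", "s1"))
#' filterEdges(edges, minSources = 2)  # keeps only A-B
#' @export
filterEdges <- function(edgeRecords, minSources = 2) {
  stopIfNot(is.data.frame(edgeRecords) && nrow(edgeRecords) > 0,
            "edgeRecords must be a non-empty data.frame")
  stopIfNot(minSources >= 1, "minSources must be >= 1")
  need <- c("geneA", "geneB", "source")
  stopIfNot(all(need %in% names(edgeRecords)),
            paste("edgeRecords must have columns", paste(need, collapse = ", ")))
  a <- trimws(as.character(edgeRecords$geneA))
  b <- trimws(as.character(edgeRecords$geneB))
  s <- trimws(as.character(edgeRecords$source))
  bad <- which(is.na(a) | is.na(b) | is.na(s) | a == "" | b == "" | s == "")
  if (length(bad))
    stop("malformed edge record(s) at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  keepRec <- a != b                      # drop self-pairs
  a <- a[keepRec]; b <- b[keepRec]; s <- s[keepRec]
  stopIfNot(length(a) > 0, "no non-self edge records")
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  nSrc <- vapply(split(s, key), function(z) length(unique(z)), integer(1))
  # preserve first-appearance order of pairs
  firstIdx <- match(unique(key), key)
  keyOrd <- key[sort(firstIdx)]
  kept <- keyOrd[nSrc[keyOrd] >= minSources]
  if (length(kept) == 0)
    stop("no edge supported by at least ", minSources, " sources", call. = FALSE)
  parts <- strsplit(kept, "\r", fixed = TRUE)
  ea <- vapply(parts, `[`, character(1), 1L)
  eb <- vapply(parts, `[`, character(1), 2L)
  # node order: first appearance among the kept edges' endpoints in input order
  nodes <- unique(c(rbind(ea, eb)))
  i <- match(ea, nodes); j <- match(eb, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  A@x[] <- 1  # collapse any doubled entries to binary
  methods::new("PPINetwork", nodes = nodes, adjacency = A)
}

#' Extract the largest connected component of a PPI network
#'
#' Ties between equal-size components are broken deterministically in favor
#' of the component containing the lexicographically smallest node
#' identifier. Node ordering of the input is preserved.
#'
#' @param net a [PPINetwork-class]
#' @return the induced [PPINetwork-class] on the largest component.
#' @export
largestComponent <- function(net) {
  stopIfNot(length(net@nodes) >= 1, "network has no nodes")
  g <- igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest contained node id decides
    minNode <- vapply(best, function(k) min(net@nodes[comp$membership == k]),
                      character(1))
    best <- best[order(minNode)[1]]
  }
  keep <- which(comp$membership == best)
  methods::new("PPINetwork", nodes = net@nodes[keep],
               adjacency = net@adjacency[keep, keep, drop = FALSE])
}

#' Column-normalize the adjacency into a transition matrix
#'
#' T[i, j] = P[i, j] / degree(j): the probability that a signal at gene j
#' steps to neighbor i. Every column of the result sums to 1.
#'
#' @param net a [PPINetwork-class] in which every node has degree >= 1
#'   (guaranteed after [largestComponent()] on a multi-node graph).
#' @return a column-stochastic sparse matrix aligned to `networkNodes(net)`.
#' @export
normalizeColumns <- function(net) {
  deg <- Matrix::colSums(net@adjacency)
  if (any(deg == 0))
    stop("zero-degree node(s) present; run largestComponent() first",
         call. = FALSE)
  tm <- net@adjacency %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(tm) <- list(net@nodes, net@nodes)
  tm
}

#' Build the seed probability vector for propagation
#'
#' Seed genes that map into the network receive equal probability mass
#' summing to 1; all other nodes 0. Unmapped seeds are reported via the
#' `nUnmapped` attribute.
#'
#' @param net a [PPINetwork-class]
#' @param seedGenes character vector of seed (driver) gene identifiers.
#' @return named numeric vector over `networkNodes(net)` summing to 1, with
#'   attribute `nUnmapped`.
#' @export
makeSeedVector <- function(net, seedGenes) {
  stopIfNot(length(seedGenes) > 0, "seedGenes must be non-empty")
  seedGenes <- unique(trimws(as.character(seedGenes)))
  mapped <- intersect(seedGenes, net@nodes)
  if (length(mapped) == 0)
    stop("none of the ", length(seedGenes), " seed genes map into the network",
         call. = FALSE)
  c0 <- stats::setNames(numeric(length(net@nodes)), net@nodes)
  c0[mapped] <- 1 / length(mapped)
  attr(c0, "nUnmapped") <- length(seedGenes) - length(mapped)
  c0
}

#' Random walk with restart over a column-stochastic transition matrix
#'
#' Iterates c_{t+1} = (1 - beta) T c_t + beta c0 from c0 until the max-norm
#' difference between successive iterates drops below `tol`, or `maxIter` is
#' reached. With a column-stochastic T and a probability seed vector, total
#' mass 1 is preserved at every step; the fixed point equals the closed form
#' beta (I - (1 - beta) T)^{-1} c0.
#'
#' @param transition column-stochastic transition matrix (from [normalizeColumns()]).
#' @param c0 seed probability vector (from [makeSeedVector()]).
#' @param beta restart probability in (0, 1]; default 0.9.
#' @param tol convergence threshold on max |c_{t+1} - c_t|; default 1e-10.
#' @param maxIter iteration cap; default 10000. Exhaustion flags
#'   `converged = FALSE` rather than erroring.
#' @return list with `scores` (named, sums to 1), `iterations`, `converged`.
#' @export
propagate <- function(transition, c0, beta = 0.9, tol = 1e-10, maxIter = 10000L) {
  stopIfNot(beta > 0 && beta <= 1, "beta must be in (0, 1]")
  stopIfNot(tol > 0, "tol must be positive")
  colSum <- Matrix::colSums(transition)
  if (any(abs(colSum - 1) > 1e-8))
    stop("transition matrix is not column-stochastic", call. = FALSE)
  stopIfNot(length(c0) == nrow(transition), "c0 length must match transition")
  ct <- as.numeric(c0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    cn <- as.numeric((1 - beta) * (transition %*% ct) + beta * as.numeric(c0))
    delta <- max(abs(cn - ct))
    ct <- cn
    if (delta < tol) { converged <- TRUE; break }
  }
  list(scores = stats::setNames(ct, names(c0)), iterations = iter,
       converged = converged)
}

#' Read / write PPI edge lists
#'
#' `readPPIEdges()` reads a TSV with columns geneA, geneB, source (one row
#' per pair-source observation). `writePPIEdges()` writes a network's edges
#' as a two-column TSV.
#'
#' @param path file path
#' @return `readPPIEdges()`: a data.frame suitable for [filterEdges()].
#' @export
readPPIEdges <- function(path) {
  utils::read.delim(path, colClasses = "character")
}

#' @rdname readPPIEdges
#' @param net a [PPINetwork-class]
#' @export
writePPIEdges <- function(net, path) {
  A <- methods::as(Matrix::triu(net@adjacency), "TsparseMatrix")
  df <- data.frame(geneA = net@nodes[A@i + 1L], geneB = net@nodes[A@j + 1L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write propagation scores as a ranked two-column TSV
#'
#' @param scores named score vector (e.g. `propagate(...)$scores`)
#' @param path output file
#' @export
writePropagationScores <- function(scores, path) {
  ord <- order(scores, decreasing = TRUE)
  utils::write.table(
    data.frame(gene = names(scores)[ord], score = unname(scores[ord])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
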