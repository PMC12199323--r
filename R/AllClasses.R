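#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t
NULL

#' PPINetwork: an undirected, unweighted protein-protein interaction network
#'
#' Wraps a symmetric binary adjacency matrix with zero diagonal, aligned to
#' an ordered vector of gene identifiers. Built by [filterEdges()] from an
#' edge list with per-source support annotations, and reduced to its largest
#' connected component by [largestComponent()] before propagation.
#'
#' @slot nodes character vector of gene identifiers (ordered; unique).
#' @slot adjacency sparse symmetric binary adjacency (`Matrix::dgCMatrix` or
#'   similar), rows/columns aligned to `nodes`, zero diagonal.
#' @seealso [filterEdges()], [largestComponent()], [propagate()]
#' @export
setClass("PPINetwork", representation(
  nodes = "character",
  adjacency = "Matrix"
))

setValidity("PPINetwork", function(object) {
  msg <- character()
  A <- object@adjacency
  n <- length(object@nodes)
  if (nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency dimensions must match number of nodes")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node identifiers")
  if (n > 0) {
    if (any(Matrix::diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
    x <- A@x %||% numeric()
    if (length(x) && !all(x %in% c(0, 1)))
      msg <- c(msg, "adjacency entries must be 0/1")
    if (!Matrix::isSymmetric(A)) msg <- c(msg, "adjacency must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PPINetwork number of nodes
#' @param x,object a `PPINetwork`
#' @export
setMethod("length", "PPINetwork", function(x) length(x@nodes))

#' Accessors for PPINetwork
#'
#' `networkNodes()` returns the ordered gene identifiers; `networkEdges()`
#' the number of undirected edges; `adjacencyMatrix()` the sparse adjacency.
#'
#' @param net a `PPINetwork`
#' @return see individual descriptions
#' @export
networkNodes <- function(net) net@nodes

#' @rdname networkNodes
#' @export
networkEdges <- function(net) as.integer(Matrix::nnzero(net@adjacency) / 2)

#' @rdname networkNodes
#' @export
adjacencyMatrix <- function(net) net@adjacency

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", length(object@nodes), "nodes and",
      networkEdges(object), "edges\n")
})

#' PathwaySignature: pathways selected from a preranked GSEA screen
#'
#' Ordered selection of pathways passing the enrichment filter
#' (ES > `esMin`, FDR < `fdrMax`, both strict), with their enrichment
#' records. Constructed by [selectSignature()].
#'
#' @slot table data.frame with columns `pathway`, `es`, `pValue`, `fdr`,
#'   `size`, ordered by ascending FDR then descending ES.
#' @slot leadingEdges named list of leading-edge gene vectors.
#' @slot esMin,fdrMax the selection thresholds applied.
#' @export
setClass("PathwaySignature", representation(
  table = "data.frame",
  leadingEdges = "list",
  esMin = "numeric",
  fdrMax = "numeric"
))

setValidity("PathwaySignature", function(object) {
  tb <- object@table
  need <- c("pathway", "es", "pValue", "fdr")
  if (!all(need %in% names(tb))) return("missing required columns")
  if (nrow(tb) == 0) return("signature must be non-empty")
  if (any(tb$es <= object@esMin)) return("all members must have es > esMin")
  if (any(tb$fdr >= object@fdrMax)) return("all members must have fdr < fdrMax")
  if (anyDuplicated(tb$pathway)) return("duplicate pathway names")
  TRUE
})

#' @describeIn PathwaySignature number of selected pathways
#' @param x,object a `PathwaySignature`
#' @export
setMethod("length", "PathwaySignature", function(x) nrow(x@table))

#' Accessors for PathwaySignature
#'
#' @param sig a `PathwaySignature`
#' @return `signaturePathways()`: character vector of pathway names in
#'   selection order; `signatureTable()`: the full enrichment table;
#'   `leadingEdges()`: named list of leading-edge genes.
#' @export
signaturePathways <- function(sig) sig@table$pathway

#' @rdname signaturePathways
#' @export
signatureTable <- function(sig) sig@table

#' @rdname signaturePathways
#' @export
leadingEdges <- function(sig) sig@leadingEdges

setMethod("show", "PathwaySignature", function(object) {
  cat("PathwaySignature:", nrow(object@table), "pathways (es >",
      object@esMin, ", fdr <", object@fdrMax, ")\n")
  print(utils::head(object@table, 5), row.names = FALSE)
  if (nrow(object@table) > 5) cat("...\n")
})

#' SyntheticCohort: a self-contained simulated drug-sensitivity cohort
#'
#' Holds every input the pipeline consumes (network, driver genes, gene-set
#' collection, expression, mutations, fingerprints, cell-drug pair table)
#' together with the generative ground truth, so that end-to-end recovery of
#' planted signal can be tested without external data. Built by
#' [simulateCohort()].
#'
#' @slot network a `PPINetwork` with planted modules.
#' @slot driverGenes character vector of planted driver genes (seed set).
#' @slot geneSets named list: pathway name -> gene members (planted modules
#'   first, then decoy sets).
#' @slot expression gene x cell log-scale expression matrix.
#' @slot mutations driver-gene x cell binary matrix.
#' @slot fingerprints bit x drug binary matrix.
#' @slot pairs data.frame (cellId, drugId, lnIC50, source).
#' @slot groundTruth list of latent variables and generative weights
#'   sufficient to recompute the noiseless response.
#' @slot spec the generating `CohortSpec` list.
#' @export
setClass("SyntheticCohort", representation(
  network = "PPINetwork",
  driverGenes = "character",
  geneSets = "list",
  expression = "matrix",
  mutations = "matrix",
  fingerprints = "matrix",
  pairs = "data.frame",
  groundTruth = "list",
  spec = "list"
))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!all(object@pairs$cellId %in% colnames(object@expression)))
    msg <- c(msg, "pair cells missing from expression")
  if (!all(object@pairs$cellId %in% colnames(object@mutations)))
    msg <- c(msg, "pair cells missing from mutations")
  if (!all(object@pairs$drugId %in% colnames(object@fingerprints)))
    msg <- c(msg, "pair drugs missing from fingerprints")
  if (!all(object@mutations %in% c(0, 1)))
    msg <- c(msg, "mutations must be binary")
  if (!all(object@fingerprints %in% c(0, 1)))
    msg <- c(msg, "fingerprints must be binary")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@expression), "genes x",
      ncol(object@expression), "cells;", ncol(object@fingerprints), "drugs;",
      nrow(object@pairs), "pairs;", length(object@geneSets), "gene sets (",
      object@spec$nPathways, "planted )\n")
})

#' DeepSensModel: trained drug-sensitivity model state
#'
#' Container for the mutation autoencoder, drug autoencoder and feedforward
#' regressor (weights, biases, batch-normalization statistics), the pathway
#' signature the activity features refer to, the training configuration and
#' the per-epoch loss history. Built by [buildModel()] / [trainEndToEnd()].
#'
#' @slot mutAE,drugAE,fnn internal network parameter lists.
#' @slot signaturePathways character vector naming the activity features.
#' @slot config training configuration list.
#' @slot history data.frame of per-epoch train/validation losses.
#' @export
setClass("DeepSensModel", representation(
  mutAE = "list",
  drugAE = "list",
  fnn = "list",
  signaturePathways = "character",
  config = "list",
  history = "data.frame"
))

setMethod("show", "DeepSensModel", function(object) {
  cat("DeepSensModel\n")
  cat("  activity features :", length(object@signaturePathways), "pathways\n")
  cat("  mutation AE       :", paste(object@mutAE$spec[c("inputDim", "h1", "h2", "bottleneck")],
                                     collapse = " -> "), "\n")
  cat("  drug AE           :", paste(object@drugAE$spec[c("inputDim", "h1", "h2", "bottleneck")],
                                     collapse = " -> "), "\n")
  if (nrow(object@history))
    cat("  trained           :", nrow(object@history), "epochs; best val loss",
        format(min(object@history$valLoss), digits = 4), "\n")
  else cat("  trained           : no\n")
})

#' @describeIn DeepSensModel per-epoch training history
#' @param model a `DeepSensModel`
#' @export
trainingHistory <- function(model) model@history
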