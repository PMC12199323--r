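## Variant classes counted as non-synonymous when binarizing mutations.
## The qualifying-class set is configurable; matching is case-insensitive
## and tolerant of underscore/space variants.
nonSynonymousClasses <- function() {
  c("missense_mutation", "missense",
    "nonsense_mutation", "nonsense",
    "frame_shift_ins", "frame_shift_del", "frameshift_insertion",
    "frameshift_deletion", "frameshift",
    "splice_site", "splice_region",
    "in_frame_ins", "in_frame_del", "inframe_insertion", "inframe_deletion",
    "nonstop_mutation", "nonstop",
    "translation_start_site", "start_codon_snp", "start_lost")
}

normalizeClass <- function(x) gsub("[ -]", "_", tolower(trimws(x)))

#' Binarize variant records into a driver-gene x sample mutation matrix
#'
#' Entry (g, s) is 1 iff at least one record for gene g in sample s carries
#' a qualifying (non-synonymous) variant class. Genes outside `driverGenes`
#' are dropped. Samples appear as columns if they carry at least one record,
#' or are listed in `sampleRoster` (all-zero columns for quiet samples).
#'
#' @param variantRecords data.frame with columns `gene`, `sample`,
#'   `variantClass` (MAF `Variant_Classification`-style labels).
#' @param driverGenes character vector; rows of the result, in this order.
#' @param sampleRoster optional character vector fixing the column set and
#'   order; default: samples observed in the records, in first appearance
#'   order.
#' @param qualifyingClasses character vector of class labels counted as
#'   non-synonymous (case/format-insensitive); see `nonSynonymousClasses()`.
#'   Unknown classes trigger one warning and do not qualify.
#' @return binary matrix, rows = driverGenes, columns = samples.
#' @export
binarizeMutations <- function(variantRecords, driverGenes,
                              sampleRoster = NULL,
                              qualifyingClasses = nonSynonymousClasses()) {
  stopIfNot(length(driverGenes) > 0, "driverGenes must be non-empty")
  need <- c("gene", "sample", "variantClass")
  stopIfNot(is.data.frame(variantRecords) && all(need %in% names(variantRecords)),
            paste("variantRecords must have columns", paste(need, collapse = ", ")))
  g <- trimws(as.character(variantRecords$gene))
  s <- trimws(as.character(variantRecords$sample))
  cls <- normalizeClass(variantRecords$variantClass)
  known <- normalizeClass(qualifyingClasses)
  synonymous <- normalizeClass(c("silent", "synonymous", "3'utr", "5'utr",
                                 "3'flank", "5'flank", "intron", "igr", "rna",
                                 "synonymous_variant"))
  unknown <- setdiff(unique(cls), c(known, synonymous))
  if (length(unknown))
    warning("unknown variant class(es) treated as non-qualifying: ",
            paste(unknown, collapse = ", "))
  driverGenes <- unique(trimws(driverGenes))
  samples <- sampleRoster %||% unique(s)
  inDriver <- g %in% driverGenes
  if (!any(inDriver))
    stop("no variant record involves a declared driver gene", call. = FALSE)
  qual <- inDriver & (cls %in% known) & (s %in% samples)
  M <- matrix(0, nrow = length(driverGenes), ncol = length(samples),
              dimnames = list(driverGenes, samples))
  if (any(qual))
    M[cbind(match(g[qual], driverGenes), match(s[qual], samples))] <- 1
  M
}

#' Log-transform a nonnegative abundance matrix
#'
#' Entrywise log_base(x + pseudocount), the standard transform applied to
#' TPM expression before modeling.
#'
#' @param tpm nonnegative numeric matrix.
#' @param base logarithm base; default 2.
#' @param pseudocount positive offset; default 1.
#' @return matrix of the same shape and dimnames.
#' @export
logTransformExpression <- function(tpm, base = 2, pseudocount = 1) {
  stopIfNot(is.numeric(tpm), "tpm must be numeric")
  stopIfNot(pseudocount > 0, "pseudocount must be > 0")
  if (any(tpm < 0)) stop("negative abundance values", call. = FALSE)
  log(tpm + pseudocount, base = base)
}

#' Circular (Morgan/ECFP) fingerprint of a molecule from SMILES
#'
#' Computes a folded circular-substructure fingerprint via OpenBabel's ECFP
#' implementation (ChemmineOB) and folds it by bitwise OR down to `nBits`
#' positions. Deterministic for a given molecular graph: equivalent SMILES
#' spellings of the same molecule give identical vectors.
#'
#' @param smiles a single SMILES string.
#' @param nBits folded fingerprint length; default 1024.
#' @param radius circular neighborhood radius; default 2 (ECFP4-equivalent).
#' @return integer 0/1 vector of length `nBits`.
#' @export
smilesToFingerprint <- function(smiles, nBits = 1024L, radius = 2L) {
  stopIfNot(is.character(smiles) && length(smiles) == 1, "smiles must be one string")
  stopIfNot(nBits >= 1, "nBits must be >= 1")
  stopIfNot(radius >= 0, "radius must be >= 0")
  if (!nzchar(trimws(smiles)))
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required for SMILES fingerprinting", call. = FALSE)
  fpName <- paste0("ECFP", 2L * radius)
  raw <- tryCatch(
    suppressWarnings(ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tmol"), identity),
      fpName)),
    error = function(e) stop("unparsable SMILES: '", smiles, "'", call. = FALSE))
  raw <- as.numeric(raw)
  if (!length(raw) || anyNA(raw))
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  folded <- integer(nBits)
  idx <- ((which(raw != 0) - 1L) %% nBits) + 1L   # fold by OR
  folded[idx] <- 1L
  folded
}

#' Fingerprint matrix for a drug table
#'
#' @param drugs data.frame with columns `drugId`, `smiles`.
#' @param nBits,radius see [smilesToFingerprint()].
#' @return bit x drug binary matrix (nBits rows).
#' @export
fingerprintMatrix <- function(drugs, nBits = 1024L, radius = 2L) {
  stopIfNot(is.data.frame(drugs) && all(c("drugId", "smiles") %in% names(drugs)),
            "drugs must have columns drugId, smiles")
  stopIfNot(!anyDuplicated(drugs$drugId), "duplicate drug identifiers")
  fp <- vapply(drugs$smiles, smilesToFingerprint, integer(nBits),
               nBits = nBits, radius = radius)
  matrix(fp, nrow = nBits,
         dimnames = list(NULL, as.character(drugs$drugId)))
}

#' Assemble the cell-drug pair table with source deduplication
#'
#' When the same (cell, drug) pair is measured in several source releases,
#' the record from the highest-precedence source is kept (e.g. a newer
#' screen supersedes an older one). Conflicting duplicates within one source
#' are an error. Row order is otherwise stable.
#'
#' @param records data.frame with columns `cellId`, `drugId`, `lnIC50`,
#'   `source`.
#' @param precedence character vector of source tags, highest precedence
#'   first; default `c("newer", "older")`. Sources absent from the list rank
#'   below all listed ones, in alphabetical order.
#' @return deduplicated data.frame (one row per pair) with the same columns.
#' @export
assemblePairs <- function(records, precedence = c("newer", "older")) {
  need <- c("cellId", "drugId", "lnIC50", "source")
  stopIfNot(is.data.frame(records) && all(need %in% names(records)),
            paste("records must have columns", paste(need, collapse = ", ")))
  stopIfNot(all(is.finite(records$lnIC50)), "lnIC50 must be finite")
  key <- paste(records$cellId, records$drugId, sep = "\r")
  skey <- paste(key, records$source, sep = "\r")
  dupWithin <- skey[duplicated(skey)]
  if (length(dupWithin)) {
    vals <- split(records$lnIC50, skey)
    conflict <- names(vals)[vapply(vals, function(v) length(unique(v)) > 1,
                                   logical(1))]
    if (length(conflict))
      stop("conflicting duplicate measurement(s) within one source: ",
           paste(gsub("\r", "/", conflict), collapse = "; "), call. = FALSE)
    keepFirst <- !duplicated(skey)
    records <- records[keepFirst, , drop = FALSE]
    key <- key[keepFirst]
  }
  extra <- sort(setdiff(unique(records$source), precedence))
  rank <- match(records$source, c(precedence, extra))
  ord <- order(rank, seq_len(nrow(records)))   # stable within rank
  recOrd <- records[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- recOrd[keep, , drop = FALSE]
  # restore input-stable row order by first appearance of each pair
  out <- out[order(match(paste(out$cellId, out$drugId, sep = "\r"),
                         unique(key))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain samples whose group reaches a minimum size
#'
#' Cohort filter dropping e.g. cancer types with fewer than 10 cell lines.
#'
#' @param groups named character/factor vector: sample -> group label.
#' @param minSize inclusive group-size threshold; default 10.
#' @return character vector of retained sample names (input order).
#' @export
filterSmallGroups <- function(groups, minSize = 10) {
  stopIfNot(minSize >= 1, "minSize must be >= 1")
  stopIfNot(!is.null(names(groups)), "groups must be a named vector")
  sizes <- table(as.character(groups))
  keep <- as.character(groups) %in% names(sizes)[sizes >= minSize]
  names(groups)[keep]
}

#' Read a gene x sample TSV matrix (first column = gene identifiers)
#'
#' @param path file path
#' @return numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname readMatrixTSV
#' @param m matrix with dimnames
#' @param idColumn name for the identifier column
#' @export
writeMatrixTSV <- function(m, path, idColumn = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-drug pair table TSV (cellId, drugId, lnIC50, source)
#'
#' @param path file path
#' @return data.frame
#' @export
readPairsTSV <- function(path) {
  df <- utils::read.delim(path, colClasses = c(cellId = "character",
                                               drugId = "character"))
  stopIfNot(all(c("cellId", "drugId", "lnIC50") %in% names(df)),
            "pair table needs columns cellId, drugId, lnIC50")
  if (is.null(df$source)) df$source <- "unspecified"
  df
}
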