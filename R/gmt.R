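#' Read and write gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' `readGMT()` drops empty member fields and errors on duplicate set names
#' or empty sets.
#'
#' @param path file path
#' @return `readGMT()`: named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  stopIfNot(length(lines) > 0, "empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT", call. = FALSE)
  sets <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    g <- g[nzchar(trimws(g))]
    if (length(g) == 0) stop("empty gene set in GMT: ", p[1], call. = FALSE)
    g
  })
  stats::setNames(sets, nm)
}

#' @rdname readGMT
#' @param sets named list of character vectors
#' @param descriptions optional character vector of per-set descriptions
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  stopIfNot(length(sets) > 0 && !is.null(names(sets)), "sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}
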