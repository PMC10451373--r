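#' Write a numeric matrix as TSV
#'
#' Header row carries column IDs; when row names are present they are
#' written as a leading `id` column. Values are formatted with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param m numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  cn <- colnames(m)
  if (is.null(cn)) cn <- sprintf("V%d", seq_len(ncol(m)))
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  if (!is.null(rownames(m))) {
    header <- paste(c("id", cn), collapse = "\t")
    body <- paste(rownames(m), body, sep = "\t")
  } else {
    header <- paste(cn, collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a numeric matrix from TSV
#'
#' Expects a header row of column IDs; a leading non-numeric column is
#' interpreted as row IDs. Ragged rows and non-numeric cells are errors
#' naming the offending line.
#'
#' @param path file path.
#' @return numeric matrix with dimnames from the file.
#' @export
readMatrixTSV <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1]))
    stop("ragged row at line ", which(widths != widths[1])[1], " of ", path)
  header <- cells[[1]]
  body <- cells[-1]
  hasRowIds <- identical(header[1], "id") ||
    (length(body) > 0 && is.na(suppressWarnings(as.numeric(body[[1]][1]))))
  rowIds <- NULL
  if (hasRowIds) {
    rowIds <- vapply(body, `[`, "", 1)
    body <- lapply(body, `[`, -1)
    header <- header[-1]
  }
  vals <- suppressWarnings(lapply(body, as.numeric))
  bad <- which(vapply(vals, anyNA, TRUE))
  if (length(bad))
    stop("non-numeric cell at line ", bad[1] + 1, " of ", path)
  m <- do.call(rbind, vals)
  if (is.null(m)) m <- matrix(numeric(), 0, length(header))
  dimnames(m) <- list(rowIds, header)
  m
}
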