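#' @include AllClasses.R
NULL

## Internal matrix container.
## Binary dialect (canonical, bit-exact round-trip):
##   magic "STMX" | int32 version=1 | 3 length-prefixed UTF-8 strings
##   (name, rowSemantics, colSemantics) | int32 nrow | int32 ncol |
##   nrow*ncol little-endian float64, column-major.
## Text dialect (human inspection): '#'-prefixed header lines, then
## tab-separated values, one row per line.

.write_string <- function(con, x) {
  b <- charToRaw(enc2utf8(x))
  writeBin(length(b), con, size = 4L, endian = "little")
  writeBin(b, con)
}

.read_string <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rawToChar(readBin(con, "raw", n))
}

#' Create a MatrixContainer
#'
#' @param values numeric matrix.
#' @param name container name.
#' @param rowSemantics,colSemantics what the axes mean
#'   (e.g. "channels", "sources").
#' @return a [MatrixContainer-class] object.
#' @export
matrixContainer <- function(values, name = "matrix",
                            rowSemantics = "rows", colSemantics = "cols") {
  stopifnot(is.matrix(values), is.numeric(values))
  new("MatrixContainer", name = name, values = values,
      rowSemantics = rowSemantics, colSemantics = colSemantics)
}

#' Write a MatrixContainer to disk
#'
#' The binary dialect (shape header plus little-endian 64-bit floats) is
#' canonical and round-trips bit-exactly; the text dialect is for human
#' inspection and round-trips to full double precision via \code{\%.17g}.
#'
#' @param x a [MatrixContainer-class], or a plain numeric matrix (wrapped).
#' @param path output file path.
#' @param format "binary" (default) or "text".
#' @return invisibly, \code{path}.
#' @seealso [readMatrixContainer()]
#' @export
writeMatrixContainer <- function(x, path, format = c("binary", "text")) {
  format <- match.arg(format)
  if (is.matrix(x)) x <- matrixContainer(x)
  stopifnot(is(x, "MatrixContainer"))
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("STMX"), con)
    writeBin(1L, con, size = 4L, endian = "little")
    .write_string(con, x@name)
    .write_string(con, x@rowSemantics)
    .write_string(con, x@colSemantics)
    writeBin(nrow(x@values), con, size = 4L, endian = "little")
    writeBin(ncol(x@values), con, size = 4L, endian = "little")
    writeBin(as.vector(x@values), con, size = 8L, endian = "little")
  } else {
    lines <- c(
      sprintf("# STMX-text name=%s", x@name),
      sprintf("# rows=%s cols=%s", x@rowSemantics, x@colSemantics),
      sprintf("# shape=%d,%d", nrow(x@values), ncol(x@values)),
      apply(x@values, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a MatrixContainer from disk
#'
#' Detects the dialect from the file's first bytes.
#'
#' @param path file written by [writeMatrixContainer()].
#' @return a [MatrixContainer-class].
#' @export
readMatrixContainer <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (identical(magic, "STMX")) {
    on.exit(close(con))
    ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (ver != 1L) stop("unsupported matrix container version: ", ver)
    nm <- .read_string(con); rs <- .read_string(con); cs <- .read_string(con)
    nr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    nc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    vals <- readBin(con, "double", nr * nc, size = 8L, endian = "little")
    return(new("MatrixContainer", name = nm, values = matrix(vals, nr, nc),
               rowSemantics = rs, colSemantics = cs))
  }
  close(con)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  nm <- sub(".*name=", "", hdr[grepl("name=", hdr)][1])
  semln <- hdr[grepl("rows=", hdr)][1]
  rs <- sub(".*rows=(\\S+).*", "\\1", semln)
  cs <- sub(".*cols=(\\S+).*", "\\1", semln)
  vals <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  new("MatrixContainer", name = nm, values = vals,
      rowSemantics = rs, colSemantics = cs)
}

## little digest used for provenance tags (not cryptographic)
.data_hash <- function(...) {
  xs <- list(...)
  acc <- 0
  for (x in xs) {
    v <- as.numeric(x)
    v <- v[is.finite(v)]
    if (length(v))
      acc <- acc + sum(v * seq_along(v) %% 997) + length(v) * 1e-3
  }
  sprintf("%.10e", acc)
}
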