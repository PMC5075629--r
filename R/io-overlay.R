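#' @include AllClasses.R
NULL

## Per-vertex statistic overlays. Two dialects:
##  * FreeSurfer-style binary overlay ("new curv"): 3-byte magic ffffff,
##    big-endian int32 vnum/fnum/vals_per_vertex, then big-endian float32
##    values. Widely produced by surface-based fMRI pipelines.
##  * plain text: one value per line, '#' comments allowed.
## Values are read as-is (never rescaled).

#' Read a per-vertex statistic overlay onto a source space
#'
#' Accepts a FreeSurfer-style binary per-vertex overlay or a plain text
#' vector file (one value per line). The overlay length must equal the
#' number of mesh vertices; vertex order is the mesh's (0-based in files).
#'
#' @param path overlay file.
#' @param mesh the [SourceSpace-class] the overlay lives on.
#' @param statType "t" (default) or "p".
#' @param dof residual degrees of freedom for a t overlay (NA allowed until
#'   thresholding).
#' @return an unthresholded [ActivationMap-class].
#' @export
readStatOverlay <- function(path, mesh, statType = c("t", "p"),
                            dof = NA_real_) {
  statType <- match.arg(statType)
  stopifnot(is(mesh, "SourceSpace"))
  if (!file.exists(path)) stop("no such overlay file: ", path)
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 3L)
  if (length(magic) == 3L && all(magic == as.raw(255L))) {
    on.exit(close(con))
    vnum <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    readBin(con, "integer", 2L, size = 4L, endian = "big") # fnum, vals/vertex
    vals <- readBin(con, "double", vnum, size = 4L, endian = "big")
  } else {
    close(con)
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    vals <- as.numeric(lines)
  }
  s <- nrow(vertices(mesh))
  if (length(vals) != s)
    stop(sprintf("overlay has %d values but the mesh has %d vertices",
                 length(vals), s))
  if (!all(is.finite(vals))) stop("overlay contains non-finite values")
  new("ActivationMap", stat = vals, statType = statType, dof = dof,
      clusterLabels = integer(0), thresholdState = "unthresholded")
}

#' Write a per-vertex statistic overlay
#'
#' @param stat numeric vector of per-vertex values, or an
#'   [ActivationMap-class] (its \code{stat} is written).
#' @param path output path.
#' @param format "freesurfer" (binary, default) or "text".
#' @return invisibly, \code{path}.
#' @export
writeStatOverlay <- function(stat, path, format = c("freesurfer", "text")) {
  format <- match.arg(format)
  if (is(stat, "ActivationMap")) stat <- stat@stat
  stopifnot(is.numeric(stat))
  if (format == "freesurfer") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(255L, 255L, 255L)), con)
    writeBin(as.integer(length(stat)), con, size = 4L, endian = "big")
    writeBin(0L, con, size = 4L, endian = "big")
    writeBin(1L, con, size = 4L, endian = "big")
    writeBin(as.numeric(stat), con, size = 4L, endian = "big")
  } else {
    writeLines(c("# per-vertex statistic overlay, 0-based vertex order",
                 sprintf("%.17g", stat)), path)
  }
  invisible(path)
}

## SourceEstimate container:
##   magic "STSE" | int32 version | double sfreq | double t0 |
##   strings method, sourceSpaceId, dataHash | int32 s | int32 d |
##   s*d float64 J (column-major) | int32 nb | nb int32 boundaries |
##   int32 nw | nw float64 per-window free energies.
## Per-window ReMLFit objects are in-memory summaries and are reduced to
## their free-energy values on disk (documented).

#' Write a SourceEstimate to the internal binary container
#'
#' Values round-trip bit-exactly; the per-window fit objects are reduced to
#' their free-energy values (full fits are in-memory objects).
#'
#' @param est a [SourceEstimate-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSourceEstimate <- function(est, path) {
  stopifnot(is(est, "SourceEstimate"))
  validObject(est)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeBin(charToRaw("STSE"), con)
  writeBin(1L, con, size = 4L, endian = "little")
  writeBin(c(est@sfreq, est@t0), con, size = 8L, endian = "little")
  .write_string(con, est@method)
  .write_string(con, est@sourceSpaceId)
  .write_string(con, est@dataHash)
  writeBin(c(nrow(est@J), ncol(est@J)), con, size = 4L, endian = "little")
  writeBin(as.vector(est@J), con, size = 8L, endian = "little")
  writeBin(length(est@windowBoundaries), con, size = 4L, endian = "little")
  writeBin(est@windowBoundaries, con, size = 4L, endian = "little")
  Fw <- vapply(est@perWindowFit, function(f) f@logEvidence, numeric(1))
  writeBin(length(Fw), con, size = 4L, endian = "little")
  if (length(Fw)) writeBin(Fw, con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a SourceEstimate written by [writeSourceEstimate()]
#'
#' @param path file path.
#' @return a [SourceEstimate-class]; per-window free energies are attached
#'   as attribute \code{"windowF"} (the full fit objects are not stored on
#'   disk).
#' @export
readSourceEstimate <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "STSE")) stop("not a SourceEstimate container: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  ft <- readBin(con, "double", 2L, size = 8L, endian = "little")
  method <- .read_string(con)
  ssid <- .read_string(con)
  hash <- .read_string(con)
  sd_ <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  J <- matrix(readBin(con, "double", sd_[1] * sd_[2], size = 8L,
                      endian = "little"), sd_[1], sd_[2])
  nb <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  bnd <- readBin(con, "integer", nb, size = 4L, endian = "little")
  nw <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  Fw <- if (nw > 0) readBin(con, "double", nw, size = 8L, endian = "little")
        else numeric(0)
  est <- new("SourceEstimate", J = J, sfreq = ft[1], t0 = ft[2],
             windowBoundaries = bnd, perWindowFit = list(),
             method = method, sourceSpaceId = ssid, dataHash = hash)
  attr(est, "windowF") <- Fw
  est
}
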