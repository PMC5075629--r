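#' @include AllClasses.R
NULL

## BrainVision triad (.vhdr / .vmrk / .eeg), multiplexed binary only,
## IEEE_FLOAT_32 or INT_16 with per-channel resolution scaling. Physical
## value = stored value * resolution, in the channel's declared unit
## (microvolts throughout this package).

.bv_parse_ini <- function(lines) {
  sec <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln) && nzchar(sec)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[sec]][[key]] <- val
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the BrainVision header/marker/data triad. Only the multiplexed
#' binary layout with IEEE float32 or 16-bit integer samples is supported
#' (the format family written by BrainVision recorders). Data are returned
#' in microvolts. Without \code{epochWindow} the whole recording is returned
#' as a single segment with \code{t0 = 0}; with it, the recording is epoched
#' around every marker of \code{markerType}.
#'
#' @param headerPath path to the \code{.vhdr} file.
#' @param epochWindow optional c(tmin, tmax) in seconds around each marker.
#' @param markerType marker class used for epoching (default "Stimulus").
#' @return an [EEGEpochs-class].
#' @export
readBrainVision <- function(headerPath, epochWindow = NULL,
                            markerType = "Stimulus") {
  if (!file.exists(headerPath))
    stop("BrainVision header file is missing: ", headerPath)
  ini <- .bv_parse_ini(readLines(headerPath, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("malformed header: no [Common Infos] section")
  dir <- dirname(headerPath)
  dataFile <- file.path(dir, ci$DataFile)
  if (!file.exists(dataFile))
    stop("BrainVision data file (.eeg) of the triad is missing: ", dataFile)
  markerFile <- if (!is.null(ci$MarkerFile)) file.path(dir, ci$MarkerFile)
                else NULL
  if (!is.null(epochWindow) &&
      (is.null(markerFile) || !file.exists(markerFile)))
    stop("BrainVision marker file (.vmrk) of the triad is missing: ",
         if (is.null(markerFile)) "(not declared in header)" else markerFile)
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "BINARY")
    stop("unsupported DataFormat: ", ci$DataFormat)
  orient <- if (is.null(ci$DataOrientation)) "MULTIPLEXED" else ci$DataOrientation
  if (toupper(orient) != "MULTIPLEXED")
    stop("unsupported DataOrientation: ", orient)
  m <- as.integer(ci$NumberOfChannels)
  sfreq <- 1e6 / as.numeric(ci$SamplingInterval)  # header stores microseconds
  fmt <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  chinfo <- ini[["Channel Infos"]]
  labels <- character(m); resol <- rep(1, m)
  for (k in seq_len(m)) {
    entry <- chinfo[[sprintf("Ch%d", k)]]
    if (is.null(entry)) stop("header missing channel entry Ch", k)
    parts <- strsplit(entry, ",")[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resol[k] <- as.numeric(parts[3])
  }
  nbytes <- file.size(dataFile)
  con <- file(dataFile, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    n <- nbytes %/% 4L
    raw <- readBin(con, "double", n, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    n <- nbytes %/% 2L
    raw <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                   endian = "little")
  } else {
    stop("unsupported BinaryFormat code: ", fmt)
  }
  d <- length(raw) %/% m
  X <- matrix(raw[seq_len(m * d)], nrow = m)  # multiplexed: channels fastest
  X <- X * resol
  if (is.null(epochWindow)) {
    arr <- array(0, c(1L, m, d))
    arr[1L, , ] <- X
    return(new("EEGEpochs", data = arr, sfreq = sfreq, t0 = 0,
               channelNames = labels, condition = "continuous"))
  }
  mk <- .bv_read_markers(markerFile)
  mk <- mk[mk$type == markerType, , drop = FALSE]
  if (nrow(mk) == 0L) stop("no markers of type '", markerType, "' found")
  pre <- round(epochWindow[1] * sfreq)
  post <- round(epochWindow[2] * sfreq)
  len <- post - pre
  keep <- mk$position + pre >= 1L & mk$position + pre + len - 1L <= d
  mk <- mk[keep, , drop = FALSE]
  arr <- array(0, c(nrow(mk), m, len))
  for (e in seq_len(nrow(mk))) {
    i0 <- mk$position[e] + pre
    arr[e, , ] <- X[, i0:(i0 + len - 1L)]
  }
  new("EEGEpochs", data = arr, sfreq = sfreq, t0 = epochWindow[1],
      channelNames = labels, condition = mk$description)
}

.bv_read_markers <- function(path) {
  ini <- .bv_parse_ini(readLines(path, warn = FALSE))
  mi <- ini[["Marker Infos"]]
  if (is.null(mi)) stop("malformed marker file: no [Marker Infos] section")
  keys <- grep("^Mk", names(mi), value = TRUE)
  recs <- lapply(keys, function(k) {
    parts <- strsplit(mi[[k]], ",")[[1]]
    data.frame(type = parts[1], description = parts[2],
               position = as.integer(parts[3]), stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write a BrainVision triad
#'
#' Writes a continuous multichannel recording (microvolts) as a BrainVision
#' header/marker/data triad — used to generate test fixtures and to export
#' simulated EEG for external tools.
#'
#' @param X numeric matrix, m channels x d samples, microvolts.
#' @param basePath path without extension; \code{.vhdr}, \code{.vmrk} and
#'   \code{.eeg} are created next to each other.
#' @param sfreq sampling rate, Hz.
#' @param channelNames channel labels (default Ch1..Chm).
#' @param binaryFormat "IEEE_FLOAT_32" (default) or "INT_16".
#' @param resolution per-channel scaling for INT_16 (stored integer *
#'   resolution = microvolts); recycled to m.
#' @param markers optional data.frame with columns type, description,
#'   position (1-based sample index).
#' @return invisibly, the header path.
#' @export
writeBrainVision <- function(X, basePath, sfreq,
                             channelNames = NULL,
                             binaryFormat = c("IEEE_FLOAT_32", "INT_16"),
                             resolution = 1,
                             markers = NULL) {
  binaryFormat <- match.arg(binaryFormat)
  stopifnot(is.matrix(X), sfreq > 0)
  m <- nrow(X)
  if (is.null(channelNames)) channelNames <- sprintf("Ch%d", seq_len(m))
  resolution <- rep_len(resolution, m)
  base <- basename(basePath)
  hdr <- paste0(basePath, ".vhdr")
  vmrk <- paste0(basePath, ".vmrk")
  eeg <- paste0(basePath, ".eeg")
  hl <- c("Brain Vision Data Exchange Header File Version 1.0",
          "[Common Infos]",
          sprintf("DataFile=%s.eeg", base),
          sprintf("MarkerFile=%s.vmrk", base),
          "DataFormat=BINARY",
          "DataOrientation=MULTIPLEXED",
          sprintf("NumberOfChannels=%d", m),
          sprintf("SamplingInterval=%.10g", 1e6 / sfreq),
          "[Binary Infos]",
          sprintf("BinaryFormat=%s", binaryFormat),
          "[Channel Infos]",
          sprintf("Ch%d=%s,,%.10g,µV", seq_len(m), channelNames,
                  resolution))
  writeLines(hl, hdr, useBytes = TRUE)
  ml <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          sprintf("DataFile=%s.eeg", base),
          "[Marker Infos]")
  if (!is.null(markers) && nrow(markers)) {
    ml <- c(ml, sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(markers)),
                        markers$type, markers$description, markers$position))
  }
  writeLines(ml, vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  if (binaryFormat == "IEEE_FLOAT_32") {
    writeBin(as.vector(X / resolution), con, size = 4L, endian = "little")
  } else {
    q <- round(sweep(X, 1L, resolution, "/"))
    if (max(abs(q)) > 32767)
      stop("INT_16 overflow: raise the resolution")
    writeBin(as.integer(q), con, size = 2L, endian = "little")
  }
  invisible(hdr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
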