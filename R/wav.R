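#' @include calibration.R
NULL

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF writer: canonical 44-byte header, one \code{fmt } chunk
#' (PCM, mono) and one \code{data} chunk. Samples are clipped to
#' [-1, 1] and quantised to signed 16-bit.
#'
#' @param samples numeric samples in [-1, 1] (or an
#'   \linkS4class{AcousticSegment}).
#' @param path output file path.
#' @param fs sampling rate, Hz (taken from the segment when one is given).
#' @return invisibly, the path.
#' @export
writeWav <- function(samples, path, fs = 48000) {
  if (is(samples, "AcousticSegment")) {
    fs <- samples@fs
    samples <- samples@samples
  }
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Counterpart of \code{\link{writeWav}}; walks the RIFF chunks, requires
#' PCM/mono/16-bit, and returns samples rescaled to [-1, 1].
#'
#' @param path WAV file path.
#' @param label optional mass label to attach, ug.
#' @return an \linkS4class{AcousticSegment}.
#' @export
readWav <- function(path, label = NA) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      if (fmt[2] != 1L) stop("only mono WAV is supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit WAV is supported")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = size %/% 2, size = 2,
                     endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(fs) || is.null(pcm)) stop("malformed WAV file: ", path)
  acousticSegment(pcm / 32767, fs = fs, label = label)
}

#' Export a dataset as WAV files plus a CSV manifest
#'
#' Writes one peak-normalised 16-bit PCM mono WAV per segment and a
#' manifest CSV with columns \code{path, label_ug, split, seed}. The
#' manifest row order, file names and audio bytes are deterministic for a
#' given dataset.
#'
#' @param ds an \linkS4class{AcousticDataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
exportDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wav <- SummarizedExperiment::assay(ds, "waveform")
  cd <- SummarizedExperiment::colData(ds)
  fs <- samplingRate(ds)
  paths <- file.path(dir, paste0(colnames(ds), ".wav"))
  for (j in seq_len(ncol(ds))) writeWav(wav[, j], paths[j], fs = fs)
  manifest <- data.frame(path = basename(paths),
                         label_ug = cd$label_ug,
                         split = cd$split,
                         seed = cd$seed)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Import a dataset from a WAV directory and manifest
#'
#' @param dir directory holding \code{manifest.csv} and the WAV files it
#'   references.
#' @return an \linkS4class{AcousticDataset}.
#' @export
importDataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  segs <- lapply(file.path(dir, manifest$path), readWav)
  fs <- segs[[1]]@fs
  mat <- vapply(segs, function(s) s@samples, numeric(length(segs[[1]]@samples)))
  colnames(mat) <- sub("\\.wav$", "", manifest$path)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(waveform = mat),
    colData = S4Vectors::DataFrame(
      label_ug = manifest$label_ug,
      split = ifelse(is.na(manifest$split) | manifest$split == "",
                     NA_character_, as.character(manifest$split)),
      seed = manifest$seed, row.names = colnames(mat)),
    metadata = list(fs = fs, duration = nrow(mat) / fs))
  as(se, "AcousticDataset")
}
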