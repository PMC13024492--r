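#' @include simulator.R
NULL

#' One-sided FFT magnitude spectrum of a segment
#'
#' For an input of length \eqn{N} sampled at \eqn{f_s}, returns the
#' \eqn{\lfloor N/2\rfloor + 1} one-sided magnitude bins at spacing
#' \eqn{f_s/N} (4800 points at 48 kHz give 2401 bins, 10 Hz apart). The
#' magnitudes are unnormalised \code{Mod(fft(x))} values; together with the
#' two-sided symmetry they satisfy Parseval's relation with the time-domain
#' energy.
#'
#' @param segment an \linkS4class{AcousticSegment} (or numeric vector, with
#'   \code{fs}).
#' @param fs sampling rate when \code{segment} is a bare vector.
#' @param zero_pad integer factor; the signal is zero-padded to
#'   \code{zero_pad * N} before the transform (1 = none). Padding refines
#'   the bin spacing for peak interpolation.
#' @return a list of class \code{"SpectralFeatures"} with elements
#'   \code{magnitudes}, \code{bin_hz}, \code{n_bins}, \code{fs}, \code{n}.
#' @examples
#' sf <- fftMagnitude(synthSegment(pvdfSpec(), seed = 1))
#' sf$n_bins # 2401
#' @export
fftMagnitude <- function(segment, fs = NULL, zero_pad = 1L) {
  if (is(segment, "AcousticSegment")) {
    x <- segment@samples
    fs <- segment@fs
  } else {
    x <- as.numeric(segment)
    if (is.null(fs)) stop("fs is required for a bare sample vector")
  }
  if (length(x) == 0L) stop("empty input")
  n0 <- length(x)
  if (zero_pad > 1L) x <- c(x, numeric((zero_pad - 1L) * n0))
  n <- length(x)
  X <- stats::fft(x)
  n_bins <- floor(n / 2) + 1L
  structure(list(magnitudes = Mod(X[seq_len(n_bins)]), bin_hz = fs / n,
                 n_bins = n_bins, fs = fs, n = n0),
            class = "SpectralFeatures")
}

#' @export
print.SpectralFeatures <- function(x, ...) {
  cat(sprintf("SpectralFeatures: %d bins at %.4g Hz spacing (fs %g Hz)\n",
              x$n_bins, x$bin_hz, x$fs))
  invisible(x)
}

# z-score with a std floor: degenerate (constant) inputs map to all-zero.
.standardize <- function(x, floor = 1e-12) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < floor) return(numeric(length(x)))
  (x - mean(x)) / s
}

#' Two-channel raw + spectrum model input
#'
#' Channel 1 is the standardized raw waveform; channel 2 is the one-sided
#' FFT magnitude linearly resampled to the waveform length and then
#' standardized. This packs the time-domain signal and its spectral
#' representation into one \code{N x 2} input tensor for the CNN and LSTM
#' classifiers.
#'
#' @inheritParams fftMagnitude
#' @return numeric matrix of dimension \code{N x 2}.
#' @export
dualChannelInput <- function(segment, fs = NULL) {
  if (is(segment, "AcousticSegment")) {
    x <- segment@samples; fs <- segment@fs
  } else {
    x <- as.numeric(segment)
    if (is.null(fs)) stop("fs is required for a bare sample vector")
  }
  n <- length(x)
  sf <- fftMagnitude(x, fs = fs)
  mag_rs <- stats::approx(seq_len(sf$n_bins), sf$magnitudes,
                          xout = seq(1, sf$n_bins, length.out = n))$y
  cbind(raw = .standardize(x), spectrum = .standardize(mag_rs))
}

#' Sliding-window patch sequence
#'
#' Segments a waveform into ordered fixed-length patches of length \code{T}
#' taken every \code{stride} samples; a trailing remainder shorter than
#' \code{T} is dropped, giving \code{floor((N - T)/stride) + 1} patches.
#' Patches are the single-channel tokens consumed by the transformer
#' classifier.
#'
#' @param segment an \linkS4class{AcousticSegment} or numeric vector.
#' @param T patch length (1 <= T <= N).
#' @param stride hop between patch starts (>= 1).
#' @param standardize logical; z-score the waveform first (default TRUE).
#' @return a list of class \code{"PatchSequence"}: \code{patches}
#'   (n_patches x T matrix), \code{T}, \code{C} (= 1), \code{n_patches},
#'   \code{stride}.
#' @examples
#' ps <- patchify(synthSegment(pvdfSpec(), seed = 1), T = 48, stride = 48)
#' ps$n_patches # 100
#' @export
patchify <- function(segment, T = 48L, stride = T, standardize = TRUE) {
  x <- if (is(segment, "AcousticSegment")) segment@samples else as.numeric(segment)
  n <- length(x)
  if (T < 1L || T > n) stop("patch length T must satisfy 1 <= T <= N")
  if (stride < 1L) stop("stride must be >= 1")
  if (standardize) x <- .standardize(x)
  starts <- seq(1L, n - T + 1L, by = stride)
  idx <- outer(starts, 0:(T - 1L), `+`)
  patches <- matrix(x[idx], nrow = length(starts), ncol = T)
  structure(list(patches = patches, T = as.integer(T), C = 1L,
                 n_patches = length(starts), stride = as.integer(stride)),
            class = "PatchSequence")
}

#' @export
print.PatchSequence <- function(x, ...) {
  cat(sprintf("PatchSequence: %d patches of length %d (stride %d, C = %d)\n",
              x$n_patches, x$T, x$stride, x$C))
  invisible(x)
}

#' Dominant spectral frequency with parabolic peak interpolation
#'
#' Finds the magnitude-spectrum argmax and refines it by three-point
#' parabolic interpolation, returning a frequency in \eqn{[0, f_s/2]}. A
#' flat spectrum returns 0 Hz with attribute \code{flat = TRUE}. For
#' sub-bin accuracy build the features with \code{zero_pad > 1}
#' (\code{\link{fftMagnitude}}).
#'
#' @param features a \code{"SpectralFeatures"} object, or an
#'   \linkS4class{AcousticSegment} (then \code{zero_pad} applies).
#' @param zero_pad padding factor used when a segment is given; default 4.
#' @return frequency, Hz, with attribute \code{flat}.
#' @examples
#' seg <- synthSegment(pvdfSpec(), delta_m = 0, noise = noiseSpec(Inf),
#'                     duration = 1, seed = 1)
#' dominantFrequency(seg) # ~8500 Hz
#' @export
dominantFrequency <- function(features, zero_pad = 4L) {
  if (is(features, "AcousticSegment")) {
    features <- fftMagnitude(features, zero_pad = zero_pad)
  }
  stopifnot(inherits(features, "SpectralFeatures"))
  m <- features$magnitudes
  if (features$n_bins < 3L) stop("need at least 3 bins")
  rng <- range(m)
  if (rng[2] - rng[1] <= 1e-12 * max(rng[2], 1e-300)) {
    return(structure(0, flat = TRUE))
  }
  k <- which.max(m)
  delta <- 0
  if (k > 1L && k < features$n_bins) {
    a <- m[k - 1L]; b <- m[k]; cc <- m[k + 1L]
    denom <- a - 2 * b + cc
    if (denom != 0) delta <- 0.5 * (a - cc) / denom
  }
  f <- (k - 1L + delta) * features$bin_hz
  structure(min(max(f, 0), features$fs / 2), flat = FALSE)
}

#' Cache featurised arrays with a JSON sidecar
#'
#' Writes a featurised input tensor to a portable binary container (RDS)
#' together with a JSON sidecar recording its provenance (architecture,
#' dimensions, sampling rate, frame/patch geometry), and reads it back.
#' \code{loadFeatures} refuses a cache whose sidecar is missing.
#'
#' @param feats a list as returned by \code{\link{featurizeDataset}}.
#' @param path file path for the binary container; the sidecar is written
#'   next to it as \code{<path>.json}.
#' @param meta named list of extra provenance fields for the sidecar.
#' @return \code{saveFeatures} the path, invisibly; \code{loadFeatures}
#'   the restored list with the sidecar under \code{$meta}.
#' @export
saveFeatures <- function(feats, path, meta = list()) {
  sidecar <- c(list(dims = dim(feats$x), n_classes = length(feats$classes),
                    classes = feats$classes), meta)
  saveRDS(feats, path)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveFeatures
#' @export
loadFeatures <- function(path) {
  if (!file.exists(paste0(path, ".json"))) {
    stop("feature cache sidecar not found: ", paste0(path, ".json"))
  }
  feats <- readRDS(path)
  feats$meta <- jsonlite::read_json(paste0(path, ".json"),
                                    simplifyVector = TRUE)
  feats
}

#' Spectral centroid of a segment
#'
#' Magnitude-weighted mean frequency; a simple monotone summary of where a
#' segment's energy sits.
#'
#' @inheritParams fftMagnitude
#' @return frequency, Hz.
#' @export
spectralCentroid <- function(segment, fs = NULL) {
  sf <- fftMagnitude(segment, fs = fs)
  freqs <- (seq_len(sf$n_bins) - 1) * sf$bin_hz
  sum(freqs * sf$magnitudes) / sum(sf$magnitudes)
}
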