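#' @include physics.R
NULL

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards. Keeps segment synthesis reproducible without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Counter-based per-segment seed derivation: any segment is reproducible in
# isolation from (master seed, index). Kept below 2^31.
.derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + as.numeric(i) * 40503) %% 2147483629 + 1)
}

#' Resonant frequency under mass load
#'
#' The loaded resonance is \eqn{f_r = f_0 + \Delta f} with \eqn{\Delta f}
#' from the thin-film relation (\code{\link{filmShift}}) applied to the
#' areal loading \eqn{\Delta m / A}; it is monotonically nonincreasing in
#' the load. \code{separation_scale} multiplies the physical shift and
#' exists purely as a synthetic-benchmark knob (see
#' \code{\link{buildDataset}}); the default of 1 is the device physics.
#'
#' @param spec a \linkS4class{ResonatorSpec} with \code{f0}, \code{rho},
#'   \code{thickness} and an area set.
#' @param delta_m mass load, ug (scalar or vector).
#' @param separation_scale multiplier on the per-unit-mass shift, default 1.
#' @return loaded resonant frequency, Hz.
#' @examples
#' loadedResonance(pvdfSpec(), 0:9)
#' @export
loadedResonance <- function(spec, delta_m, separation_scale = 1) {
  vapply(delta_m, function(m) {
    spec@f0 + separation_scale * filmShift(spec, m)
  }, numeric(1))
}

#' Second-order resonator magnitude response
#'
#' \deqn{|H(f)| = \left[(1 - (f/f_r)^2)^2 + (f/(f_r Q))^2\right]^{-1/2},}
#' the DC-normalised gain of a damped second-order resonator with the
#' spec's quality factor: unity at DC, peak gain close to \eqn{Q} at
#' \eqn{f \approx f_r}, half-power width close to \eqn{f_r/Q} for
#' \eqn{Q \gg 1}.
#'
#' @param spec a \linkS4class{ResonatorSpec} with \code{Q} set.
#' @param f evaluation frequency, Hz (vectorised).
#' @param fr resonant frequency, Hz; defaults to the unloaded \code{f0}.
#' @return dimensionless gain.
#' @export
amplitudeResponse <- function(spec, f, fr = spec@f0) {
  .need(spec, "Q")
  if (any(fr <= 0)) stop("fr must be > 0")
  r <- f / fr
  1 / sqrt((1 - r^2)^2 + (r / spec@Q)^2)
}

# Phase of the same second-order response.
.response_phase <- function(spec, f, fr) {
  r <- f / fr
  atan2(-r / spec@Q, 1 - r^2)
}

# Fourier-series harmonics of the drive waveform, truncated at Nyquist.
.harmonics <- function(waveform, f_exc, nyquist) {
  k_max <- max(1, floor((nyquist - 1e-9) / f_exc))
  switch(waveform,
    sine = data.frame(k = 1, amp = 1),
    square = {
      k <- seq(1, k_max, by = 2)
      data.frame(k = k, amp = 4 / (pi * k))
    },
    triangle = {
      k <- seq(1, k_max, by = 2)
      data.frame(k = k, amp = 8 / pi^2 * (-1)^((k - 1) / 2) / k^2)
    },
    stop("unknown waveform: ", waveform))
}

# Unit-power 1/f ("pink") noise via spectral shaping of white noise.
.pink_noise <- function(n) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f_idx <- c(1, pmin(seq_len(n - 1), n - seq_len(n - 1))) # symmetric bin index
  scale <- c(0, 1 / sqrt(f_idx[-1]))
  p <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  p / stats::sd(p)
}

#' Synthesize one acoustic segment from the driven microbalance
#'
#' Models the capture chain: the drive waveform's Fourier harmonics are
#' weighted by the resonator magnitude and phase response at the loaded
#' resonance \eqn{f_r} (see \code{\link{loadedResonance}}), summed in
#' steady state, scaled to unit peak, and additive microphone noise
#' realising \code{noise@snr_db} is applied, followed by peak
#' normalisation. With the default resonance-tracking excitation the
#' emitted tone sits at \eqn{f_r}, so the mass class is encoded in the
#' spectral position; with a fixed drive frequency the class is encoded in
#' the harmonic weighting by \eqn{|H|}.
#'
#' Identical arguments and seed give an identical sample sequence.
#'
#' @param spec a \linkS4class{ResonatorSpec}.
#' @param excitation an \linkS4class{ExcitationSpec}.
#' @param delta_m mass load, ug.
#' @param noise a \linkS4class{NoiseSpec}.
#' @param fs sampling rate, Hz; must exceed twice the drive frequency.
#' @param duration segment length, s (> 0).
#' @param seed RNG seed for phase and noise.
#' @param separation_scale benchmark knob multiplying the mass-induced
#'   shift; 1 is the device physics.
#' @return an \linkS4class{AcousticSegment} labelled with \code{delta_m}.
#' @examples
#' seg <- synthSegment(pvdfSpec(), delta_m = 3, seed = 7)
#' seg
#' @export
synthSegment <- function(spec, excitation = excitationSpec(), delta_m = 0,
                         noise = noiseSpec(), fs = 48000, duration = 0.1,
                         seed = 1, separation_scale = 1) {
  if (duration <= 0) stop("duration must be > 0")
  n <- round(fs * duration)
  fr <- loadedResonance(spec, delta_m, separation_scale)
  f_exc <- if (is.na(excitation@frequency)) fr else excitation@frequency
  if (fs <= 2 * f_exc) {
    stop(sprintf("sampling rate %g Hz violates Nyquist for drive at %g Hz",
                 fs, f_exc))
  }
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    phi0 <- stats::runif(1, 0, 2 * pi)
    s <- numeric(n)
    if (excitation@amplitude > 0) {
      h <- .harmonics(excitation@waveform, f_exc, fs / 2)
      for (j in seq_len(nrow(h))) {
        fk <- h$k[j] * f_exc
        gain <- amplitudeResponse(spec, fk, fr)
        ph <- .response_phase(spec, fk, fr)
        s <- s + h$amp[j] * gain * sin(2 * pi * fk * t + h$k[j] * phi0 + ph)
      }
      pk <- max(abs(s))
      if (pk > 0) s <- s / pk # unit peak before noise
    }
    x <- s
    if (is.finite(noise@snr_db)) {
      p_ref <- mean(s^2)
      if (p_ref == 0) p_ref <- 0.5 # pure-noise segments: unit-peak sine reference
      p_noise <- p_ref / 10^(noise@snr_db / 10)
      pf <- noise@pink_fraction
      nz <- numeric(n)
      if (pf < 1) nz <- nz + sqrt(1 - pf) * stats::rnorm(n)
      if (pf > 0) nz <- nz + sqrt(pf) * .pink_noise(n)
      x <- x + sqrt(p_noise) * nz
    }
    pk <- max(abs(x))
    if (pk > 1) x <- x / pk # no clipping beyond +/-1
    acousticSegment(x, fs = fs, label = delta_m)
  })
}

#' Build a labelled synthetic dataset
#'
#' Generates \code{length(classes) * n_per_class} segments with exact class
#' balance. Generation order is randomised (emulating a randomised
#' mass-load sequence across acquisition sessions) and each segment's seed
#' is derived deterministically from the master seed, so the whole dataset
#' -- or any single segment -- is reproducible.
#'
#' @param spec,excitation,noise,fs,duration,separation_scale as in
#'   \code{\link{synthSegment}}.
#' @param classes distinct mass-load classes, ug (default 0:9).
#' @param n_per_class segments per class.
#' @param seed master seed.
#' @return an \linkS4class{AcousticDataset} (split unassigned).
#' @examples
#' ds <- buildDataset(pvdfSpec(), n_per_class = 3, seed = 1)
#' ds
#' @export
buildDataset <- function(spec, excitation = excitationSpec(), classes = 0:9,
                         n_per_class = 250, noise = noiseSpec(), fs = 48000,
                         duration = 0.1, seed = 1, separation_scale = 1) {
  if (length(classes) == 0L) stop("classes must be nonempty")
  if (anyDuplicated(classes)) stop("duplicate class labels")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  labels <- rep(classes, each = n_per_class)
  ord <- with_seed(seed, sample.int(length(labels)))
  labels <- labels[ord]
  n <- round(fs * duration)
  seeds <- vapply(seq_along(labels), function(i) .derive_seed(seed, i),
                  integer(1))
  mat <- matrix(0, nrow = n, ncol = length(labels))
  for (i in seq_along(labels)) {
    seg <- synthSegment(spec, excitation, labels[i], noise, fs, duration,
                        seed = seeds[i], separation_scale = separation_scale)
    mat[, i] <- seg@samples
  }
  colnames(mat) <- sprintf("seg%05d", seq_along(labels))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(waveform = mat),
    colData = S4Vectors::DataFrame(
      label_ug = labels, split = NA_character_, seed = seeds,
      row.names = colnames(mat)),
    metadata = list(fs = fs, duration = duration, spec = spec,
                    excitation = excitation, noise = noise,
                    separation_scale = separation_scale, seed = seed))
  as(se, "AcousticDataset")
}

#' Extract one segment from a dataset
#'
#' @param ds an \linkS4class{AcousticDataset}.
#' @param i column index.
#' @return an \linkS4class{AcousticSegment}.
#' @export
getSegment <- function(ds, i) {
  stopifnot(i >= 1, i <= ncol(ds))
  acousticSegment(SummarizedExperiment::assay(ds, "waveform")[, i],
                  fs = samplingRate(ds), label = massLabels(ds)[i])
}
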