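#' @include train-eval.R
NULL

#' Ordinary least-squares calibration of shift against mass
#'
#' Fits \eqn{\Delta f = a + b\,\Delta m} (or \eqn{\Delta f = b\,\Delta m}
#' through the origin) and reports the slope (Hz/ug; its negation is the
#' empirical sensitivity \eqn{S_m}), intercept and coefficient of
#' determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. Physically generated
#' calibration sets have a negative slope.
#'
#' @param delta_m mass loads, ug (>= 2 values, at least two distinct).
#' @param delta_f matching frequency shifts, Hz.
#' @param through_origin force a zero intercept.
#' @return a \linkS4class{CalibrationFit}.
#' @examples
#' fitCalibration(0:9, -5 * (0:9))
#' @export
fitCalibration <- function(delta_m, delta_f, through_origin = FALSE) {
  if (length(delta_m) != length(delta_f)) stop("lengths differ")
  if (length(delta_m) < 2L) stop("need at least 2 calibration points")
  if (length(unique(delta_m)) < 2L) {
    stop("degenerate calibration: all mass loads identical")
  }
  fit <- if (through_origin) stats::lm(delta_f ~ delta_m + 0)
         else stats::lm(delta_f ~ delta_m)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- if (through_origin) sum(delta_f^2) else sum((delta_f - mean(delta_f))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else ifelse(ss_res == 0, 1, 0)
  new("CalibrationFit",
      slope = unname(if (through_origin) co["delta_m"] else co["delta_m"]),
      intercept = unname(if (through_origin) 0 else co["(Intercept)"]),
      r_squared = max(0, min(1, r2)),
      n_points = length(delta_m),
      through_origin = through_origin)
}

#' Invert a calibration fit to a mass estimate
#'
#' \eqn{\Delta m = (\Delta f - \mathrm{intercept})/\mathrm{slope}}; exact
#' round-trip with the fitted line.
#'
#' @param fit a \linkS4class{CalibrationFit} with nonzero slope.
#' @param delta_f measured frequency shift(s), Hz.
#' @return mass estimate(s), ug.
#' @export
predictMass <- function(fit, delta_f) {
  if (fit@slope == 0) stop("cannot invert a zero-slope calibration")
  (delta_f - fit@intercept) / fit@slope
}

#' Measure frequency shifts from simulated segments
#'
#' Synthesizes one segment per mass load (default 1 s -- ten times the
#' classification window, to push the spectral resolution well below the
#' per-microgram shift), estimates each segment's dominant frequency by
#' interpolated FFT peak, and returns the shifts relative to the measured
#' unloaded resonance.
#'
#' @param spec a \linkS4class{ResonatorSpec}.
#' @param masses mass loads, ug.
#' @param noise a \linkS4class{NoiseSpec}; default noiseless.
#' @param duration segment length, s.
#' @param fs sampling rate, Hz.
#' @param seed master seed (one derived seed per segment).
#' @param excitation an \linkS4class{ExcitationSpec}.
#' @return data.frame(delta_m_ug, f_hz, delta_f_hz).
#' @export
measureShifts <- function(spec, masses = 0:9, noise = noiseSpec(Inf),
                          duration = 1, fs = 48000, seed = 1,
                          excitation = excitationSpec()) {
  f_est <- vapply(seq_along(masses), function(i) {
    seg <- synthSegment(spec, excitation, masses[i], noise, fs, duration,
                        seed = .derive_seed(seed, i))
    as.numeric(dominantFrequency(seg))
  }, numeric(1))
  f0_est <- if (any(masses == 0)) f_est[match(0, masses)] else spec@f0
  data.frame(delta_m_ug = masses, f_hz = f_est, delta_f_hz = f_est - f0_est)
}

#' End-to-end calibration from the simulator
#'
#' Convenience wrapper: \code{\link{measureShifts}} then
#' \code{\link{fitCalibration}}.
#'
#' @inheritParams measureShifts
#' @inheritParams fitCalibration
#' @return list(fit = \linkS4class{CalibrationFit}, shifts = data.frame).
#' @export
calibrateFromSimulator <- function(spec, masses = 0:9, noise = noiseSpec(Inf),
                                   duration = 1, fs = 48000, seed = 1,
                                   through_origin = FALSE) {
  shifts <- measureShifts(spec, masses, noise, duration, fs, seed)
  list(fit = fitCalibration(shifts$delta_m_ug, shifts$delta_f_hz,
                            through_origin = through_origin),
       shifts = shifts)
}

#' Replicated noisy-calibration study
#'
#' For each replicate, the exact thin-film shifts over \code{masses} are
#' perturbed with Gaussian frequency noise whose standard deviation is
#' \code{noise_sd_frac} of the full-scale shift, and an OLS line is
#' fitted. Returns the per-replicate \eqn{R^2}, whose distribution
#' quantifies how robustly the linearity survives measurement noise.
#'
#' @param spec a \linkS4class{ResonatorSpec}.
#' @param masses calibration masses, ug.
#' @param noise_sd_frac frequency-noise sd as a fraction of the full-scale
#'   shift (default 0.01).
#' @param n_rep number of replicates.
#' @param seed RNG seed.
#' @return numeric vector of \eqn{R^2}, length \code{n_rep}.
#' @examples
#' r2 <- calibrationNoiseStudy(pvdfSpec(), n_rep = 20, seed = 1)
#' median(r2)
#' @export
calibrationNoiseStudy <- function(spec, masses = 0:9, noise_sd_frac = 0.01,
                                  n_rep = 200, seed = 0) {
  shifts <- vapply(masses, function(m) filmShift(spec, m), numeric(1))
  full_scale <- max(abs(shifts))
  sd_hz <- noise_sd_frac * full_scale
  with_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      noisy <- shifts + stats::rnorm(length(shifts), sd = sd_hz)
      fitCalibration(masses, noisy)@r_squared
    }, numeric(1))
  })
}
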