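#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a resonator specification
#'
#' Practical units at the interface: thickness in micrometres, diameter in
#' millimetres, mass elsewhere in micrograms. Internally everything is CGS
#' (g, cm, s, Hz). The active area may be given directly (cm^2) or derived
#' from a circular active region of the given diameter. Either \code{q} or
#' \code{bandwidth_hz} (or both, consistently) may be supplied.
#'
#' @param f0_hz unloaded fundamental resonant frequency, Hz.
#' @param q quality factor (dimensionless); derived from the bandwidth if
#'   only that is given.
#' @param diameter_mm active-region diameter, mm.
#' @param area_cm2 piezoelectrically active area, cm^2.
#' @param rho_g_cm3 film material density, g/cm^3.
#' @param thickness_um film thickness, um.
#' @param rho_q substrate density, g/cm^3 (Sauerbrey form).
#' @param mu_q substrate shear modulus, g cm^-1 s^-2 (Sauerbrey form).
#' @param bandwidth_hz half-power bandwidth, Hz.
#' @return a \linkS4class{ResonatorSpec}.
#' @examples
#' # the 28 um / 5 mm PVDF device resonating at 8.5 kHz with Q = 27.6
#' pvdfSpec()
#' @export
resonatorSpec <- function(f0_hz, q = NA, diameter_mm = NA, area_cm2 = NA,
                          rho_g_cm3 = NA, thickness_um = NA, rho_q = NA,
                          mu_q = NA, bandwidth_hz = NA) {
  q <- .opt_na(q); bandwidth_hz <- .opt_na(bandwidth_hz)
  area_cm2 <- .opt_na(area_cm2); diameter_mm <- .opt_na(diameter_mm)
  if (is.na(q) && !is.na(bandwidth_hz)) q <- f0_hz / bandwidth_hz
  if (is.na(area_cm2) && !is.na(diameter_mm)) {
    area_cm2 <- pi * (diameter_mm / 20)^2
  }
  new("ResonatorSpec",
    f0 = as.numeric(f0_hz), Q = q, A = area_cm2, diameter = diameter_mm,
    rho = .opt_na(rho_g_cm3), thickness = .opt_na(thickness_um) * 1e-4,
    rho_q = .opt_na(rho_q), mu_q = .opt_na(mu_q), bandwidth = bandwidth_hz)
}

#' Default PVDF microbalance device
#'
#' The flexible PVDF diaphragm characterised in this package's worked
#' examples: 28 um film on a 5 mm active region, fundamental resonance
#' 8.5 kHz, measured Q of 27.6 (half-power bandwidth 308 Hz). The PVDF
#' density default of 1.78 g/cm^3 is a standard literature value for poled
#' beta-phase film.
#'
#' @param rho_g_cm3 PVDF film density, g/cm^3.
#' @return a \linkS4class{ResonatorSpec}.
#' @export
pvdfSpec <- function(rho_g_cm3 = 1.78) {
  resonatorSpec(f0_hz = 8500, q = 27.6, diameter_mm = 5,
                rho_g_cm3 = rho_g_cm3, thickness_um = 28)
}

#' Construct a mass load
#'
#' @param delta_m_ug total added mass, ug.
#' @param delta_mA areal mass loading, g/cm^2.
#' @param area_cm2 active area used to cross-derive the missing field.
#' @return a \linkS4class{MassLoad}.
#' @export
massLoad <- function(delta_m_ug = NA, delta_mA = NA, area_cm2 = NA) {
  delta_m_ug <- .opt_na(delta_m_ug); delta_mA <- .opt_na(delta_mA)
  area_cm2 <- .opt_na(area_cm2)
  if (!is.na(area_cm2)) {
    if (is.na(delta_mA) && !is.na(delta_m_ug)) {
      delta_mA <- delta_m_ug * 1e-6 / area_cm2
    } else if (is.na(delta_m_ug) && !is.na(delta_mA)) {
      delta_m_ug <- delta_mA * area_cm2 * 1e6
    } else if (!is.na(delta_m_ug) && !is.na(delta_mA)) {
      if (abs(delta_mA - delta_m_ug * 1e-6 / area_cm2) >
          1e-9 * max(delta_mA, 1e-300)) {
        stop("delta_m and delta_mA inconsistent for the given area")
      }
    }
  }
  new("MassLoad", delta_m = delta_m_ug, delta_mA = delta_mA)
}

#' Construct an excitation specification
#'
#' @param waveform "sine", "square" or "triangle".
#' @param frequency_hz drive frequency, Hz; NA (default) tracks the loaded
#'   resonance, emulating an operator tuning the generator to resonance.
#' @param amplitude linear drive amplitude; 0 produces pure-noise segments.
#' @return an \linkS4class{ExcitationSpec}.
#' @export
excitationSpec <- function(waveform = c("sine", "square", "triangle"),
                           frequency_hz = NA, amplitude = 1) {
  waveform <- match.arg(waveform)
  new("ExcitationSpec", waveform = waveform,
      frequency = .opt_na(frequency_hz), amplitude = as.numeric(amplitude))
}

#' Construct a noise specification
#'
#' @param snr_db target signal-to-noise ratio, dB; Inf disables noise.
#' @param pink_fraction share of 1/f noise in the total noise power, [0,1].
#' @return a \linkS4class{NoiseSpec}.
#' @export
noiseSpec <- function(snr_db = 30, pink_fraction = 0) {
  new("NoiseSpec", snr_db = as.numeric(snr_db),
      pink_fraction = as.numeric(pink_fraction))
}

#' Construct a single acoustic segment
#'
#' @param samples numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param label mass-load class, ug, or NA.
#' @return an \linkS4class{AcousticSegment}.
#' @export
acousticSegment <- function(samples, fs = 48000, label = NA) {
  new("AcousticSegment", samples = as.numeric(samples), fs = as.numeric(fs),
      label = .opt_na(label))
}

#' @describeIn accessors unloaded resonance of a device spec
#' @export
setMethod("resonantFrequency", "ResonatorSpec", function(object) object@f0)

#' @describeIn accessors quality factor of a device spec
#' @export
setMethod("qFactor", "ResonatorSpec", function(object) object@Q)

#' @describeIn accessors active area (cm^2) of a device spec
#' @export
setMethod("activeArea", "ResonatorSpec", function(object) object@A)

#' @describeIn accessors sampling rate of a segment
#' @export
setMethod("samplingRate", "AcousticSegment", function(object) object@fs)

#' @describeIn accessors sampling rate of a dataset
#' @export
setMethod("samplingRate", "AcousticDataset",
          function(object) S4Vectors::metadata(object)$fs)

#' @describeIn accessors per-segment class labels (ug) of a dataset
#' @export
setMethod("massLabels", "AcousticDataset",
          function(object) SummarizedExperiment::colData(object)$label_ug)

#' @describeIn accessors per-segment split assignment of a dataset
#' @export
setMethod("splitOf", "AcousticDataset",
          function(object) SummarizedExperiment::colData(object)$split)

setMethod("show", "ResonatorSpec", function(object) {
  cat("ResonatorSpec\n")
  cat(sprintf("  f0: %g Hz   Q: %s   half-power BW: %s Hz\n", object@f0,
              ifelse(is.na(object@Q), "NA", sprintf("%.1f", object@Q)),
              ifelse(is.na(object@Q), "NA", format(object@f0 / object@Q, digits = 4))))
  cat(sprintf("  active area: %s cm^2 (diameter %s mm)\n",
              format(object@A, digits = 4), format(object@diameter)))
  cat(sprintf("  film: rho = %s g/cm^3, thickness = %s um\n",
              format(object@rho), format(object@thickness * 1e4)))
  if (!is.na(object@rho_q) || !is.na(object@mu_q)) {
    cat(sprintf("  substrate: rho_q = %s g/cm^3, mu_q = %s g/(cm s^2)\n",
                format(object@rho_q), format(object@mu_q, digits = 4)))
  }
  invisible(object)
})

setMethod("show", "AcousticSegment", function(object) {
  cat(sprintf("AcousticSegment: %d samples @ %g Hz (%.4g s)%s\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              ifelse(is.na(object@label), "",
                     sprintf(", label %g ug", object@label))))
  invisible(object)
})

setMethod("show", "AcousticDataset", function(object) {
  md <- S4Vectors::metadata(object)
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("AcousticDataset: %d segments x %d samples @ %s Hz\n",
              ncol(object), nrow(object), format(md$fs)))
  cat(sprintf("  classes (ug): %s\n",
              paste(sort(unique(cd$label_ug)), collapse = " ")))
  sp <- table(factor(cd$split, levels = c("train", "val", "test")),
              useNA = "ifany")
  cat("  split:", paste(names(sp), as.integer(sp), sep = "=", collapse = " "),
      "\n")
  invisible(object)
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: %d classes, %d samples, accuracy %.4f\n",
              nrow(object@counts), sum(object@counts),
              sum(diag(object@counts)) / sum(object@counts)))
  print(object@counts)
  invisible(object)
})

setMethod("show", "CalibrationFit", function(object) {
  cat("CalibrationFit (frequency shift vs mass load)\n")
  cat(sprintf("  slope: %.4f Hz/ug   intercept: %.4f Hz   R^2: %.6f   n = %d\n",
              object@slope, object@intercept, object@r_squared,
              object@n_points))
  cat(sprintf("  empirical sensitivity S_m = %.4f Hz/ug\n", -object@slope))
  invisible(object)
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: %s, %d trainable parameters\n",
              object@arch, countParams(object)))
  if (!is.null(object@meta$history)) {
    h <- object@meta$history
    cat(sprintf("  trained %d epochs, best val accuracy %.4f\n",
                nrow(h), max(h$val_accuracy)))
  } else {
    cat("  untrained (freshly initialised)\n")
  }
  invisible(object)
})
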