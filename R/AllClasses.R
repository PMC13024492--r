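#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats fft lm coef predict rnorm runif sd approx var
#' @importFrom utils write.csv read.csv head
NULL

.opt_na <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)

#' Physical description of the resonant sensing element
#'
#' A \code{ResonatorSpec} bundles the device constants that all
#' frequency--mass relations consume: the unloaded fundamental resonance
#' \code{f0} (Hz), the quality factor \code{Q}, the active area (cm^2, also
#' derivable from the active-region diameter in mm), the piezoelectric film
#' density (g/cm^3) and thickness (stored in cm), and -- for the Sauerbrey
#' form -- the substrate density \code{rho_q} (g/cm^3) and shear modulus
#' \code{mu_q} (g cm^-1 s^-2). Optional slots may be \code{NA}; operations
#' that need them raise a configuration error.
#'
#' All internal computation is in CGS units (g, cm, s, Hz); the constructor
#' accepts practical units (thickness in um, diameter in mm) and converts.
#'
#' @slot f0 numeric(1), unloaded fundamental resonant frequency, Hz.
#' @slot Q numeric(1), quality factor (dimensionless), or NA.
#' @slot A numeric(1), piezoelectrically active area, cm^2, or NA.
#' @slot diameter numeric(1), active-region diameter, mm, or NA.
#' @slot rho numeric(1), film material density, g/cm^3, or NA.
#' @slot thickness numeric(1), film thickness, cm, or NA.
#' @slot rho_q numeric(1), substrate density, g/cm^3, or NA.
#' @slot mu_q numeric(1), substrate shear modulus, g cm^-1 s^-2, or NA.
#' @slot bandwidth numeric(1), half-power bandwidth, Hz, or NA.
#' @exportClass ResonatorSpec
setClass("ResonatorSpec",
  representation(
    f0 = "numeric", Q = "numeric", A = "numeric", diameter = "numeric",
    rho = "numeric", thickness = "numeric", rho_q = "numeric",
    mu_q = "numeric", bandwidth = "numeric"
  ),
  prototype(
    f0 = NA_real_, Q = NA_real_, A = NA_real_, diameter = NA_real_,
    rho = NA_real_, thickness = NA_real_, rho_q = NA_real_,
    mu_q = NA_real_, bandwidth = NA_real_
  )
)

setValidity("ResonatorSpec", function(object) {
  msg <- character()
  chk_pos <- function(val, name) {
    if (!is.na(val) && val <= 0) sprintf("%s must be > 0", name) else NULL
  }
  if (is.na(object@f0) || object@f0 <= 0) {
    msg <- c(msg, "f0 must be set and > 0")
  }
  for (nm in c("Q", "A", "diameter", "rho", "thickness", "rho_q", "mu_q",
               "bandwidth")) {
    msg <- c(msg, chk_pos(slot(object, nm), nm))
  }
  if (!is.na(object@Q) && !is.na(object@bandwidth)) {
    if (abs(object@Q - object@f0 / object@bandwidth) / object@Q >= 1e-6) {
      msg <- c(msg, "Q and bandwidth inconsistent: Q must equal f0/bandwidth")
    }
  }
  if (!is.na(object@A) && !is.na(object@diameter)) {
    A_circ <- pi * (object@diameter / 20)^2 # mm diameter -> cm radius
    if (abs(object@A - A_circ) / object@A >= 1e-6) {
      msg <- c(msg, "A inconsistent with circular area from diameter")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Mass load on the sensing surface
#'
#' Total added mass \code{delta_m} (ug) and/or areal mass loading
#' \code{delta_mA} (g/cm^2). When both are given together with an area they
#' must agree.
#'
#' @slot delta_m numeric(1), total added mass, ug, or NA.
#' @slot delta_mA numeric(1), areal mass loading, g/cm^2, or NA.
#' @exportClass MassLoad
setClass("MassLoad",
  representation(delta_m = "numeric", delta_mA = "numeric"),
  prototype(delta_m = NA_real_, delta_mA = NA_real_)
)

setValidity("MassLoad", function(object) {
  msg <- character()
  if (!is.na(object@delta_m) && object@delta_m < 0) {
    msg <- c(msg, "delta_m must be >= 0")
  }
  if (!is.na(object@delta_mA) && object@delta_mA < 0) {
    msg <- c(msg, "delta_mA must be >= 0")
  }
  if (is.na(object@delta_m) && is.na(object@delta_mA)) {
    msg <- c(msg, "at least one of delta_m, delta_mA must be set")
  }
  if (length(msg)) msg else TRUE
})

#' Theoretical and empirical mass sensitivity
#'
#' @slot S_M numeric(1), theoretical sensitivity from device constants
#'   (magnitude of frequency shift per unit mass); unit in \code{S_M_unit}.
#' @slot S_M_unit character(1), either "Hz per g/cm2" (areal) or "Hz/ug"
#'   (area-normalised).
#' @slot S_m numeric(1), empirically calibrated sensitivity, Hz/ug, or NA.
#' @exportClass SensitivityResult
setClass("SensitivityResult",
  representation(S_M = "numeric", S_M_unit = "character", S_m = "numeric"),
  prototype(S_M = NA_real_, S_M_unit = NA_character_, S_m = NA_real_)
)

#' Electrical excitation applied to the resonator
#'
#' @slot waveform character(1), one of "sine", "square", "triangle".
#' @slot frequency numeric(1), drive frequency in Hz, or NA to track the
#'   loaded resonance (the operator tunes the generator to resonance).
#' @slot amplitude numeric(1), linear drive amplitude (arbitrary units);
#'   0 yields pure noise segments.
#' @exportClass ExcitationSpec
setClass("ExcitationSpec",
  representation(waveform = "character", frequency = "numeric",
                 amplitude = "numeric"),
  prototype(waveform = "sine", frequency = NA_real_, amplitude = 1)
)

setValidity("ExcitationSpec", function(object) {
  msg <- character()
  if (!object@waveform %in% c("sine", "square", "triangle")) {
    msg <- c(msg, "waveform must be one of 'sine', 'square', 'triangle'")
  }
  if (!is.na(object@frequency) && object@frequency <= 0) {
    msg <- c(msg, "frequency must be > 0 (or NA to track resonance)")
  }
  if (is.na(object@amplitude) || object@amplitude < 0) {
    msg <- c(msg, "amplitude must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Additive sensor/microphone noise description
#'
#' @slot snr_db numeric(1), target signal-to-noise ratio in dB
#'   (\code{Inf} disables noise).
#' @slot pink_fraction numeric(1) in [0,1], share of 1/f noise in the total
#'   noise power; the remainder is white Gaussian.
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(snr_db = "numeric", pink_fraction = "numeric"),
  prototype(snr_db = 30, pink_fraction = 0)
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (is.na(object@snr_db)) msg <- c(msg, "snr_db must be set")
  if (is.na(object@pink_fraction) || object@pink_fraction < 0 ||
      object@pink_fraction > 1) {
    msg <- c(msg, "pink_fraction must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' One labelled mono acoustic segment
#'
#' @slot samples numeric vector of audio samples.
#' @slot fs numeric(1), sampling rate, Hz.
#' @slot label numeric(1), mass-load class in ug, or NA when unlabelled.
#' @exportClass AcousticSegment
setClass("AcousticSegment",
  representation(samples = "numeric", fs = "numeric", label = "numeric"),
  prototype(samples = numeric(), fs = 48000, label = NA_real_)
)

setValidity("AcousticSegment", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (length(object@samples) < 1L) msg <- c(msg, "samples must be nonempty")
  if (length(msg)) msg else TRUE
})

#' Labelled collection of acoustic segments
#'
#' An \code{AcousticDataset} extends \code{SummarizedExperiment}: the single
#' assay \code{"waveform"} is a samples-by-segments numeric matrix, and the
#' column data carry per-segment \code{label_ug}, \code{split}
#' (train/val/test or NA) and the derived generator \code{seed}. Generator
#' provenance (sampling rate, duration, device, excitation, noise, master
#' seed) lives in \code{metadata()}.
#'
#' @exportClass AcousticDataset
setClass("AcousticDataset", contains = "SummarizedExperiment")

setValidity("AcousticDataset", function(object) {
  msg <- character()
  if (!"waveform" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'waveform' is required")
  }
  cd <- SummarizedExperiment::colData(object)
  for (nm in c("label_ug", "split", "seed")) {
    if (!nm %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", nm))
  }
  if ("split" %in% colnames(cd)) {
    ok <- cd$split %in% c("train", "val", "test") | is.na(cd$split)
    if (!all(ok)) msg <- c(msg, "split must be train/val/test or NA")
  }
  if (length(msg)) msg else TRUE
})

#' K x K confusion matrix of classification counts
#'
#' Rows are true classes, columns predicted classes; entries are
#' nonnegative integer counts. Class labels are the mass loads in ug.
#'
#' @slot counts integer matrix, K x K.
#' @slot class_labels numeric vector of K class labels (ug).
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", class_labels = "numeric")
)

setValidity("ConfusionMatrix", function(object) {
  msg <- character()
  cm <- object@counts
  if (nrow(cm) != ncol(cm)) msg <- c(msg, "counts must be square")
  if (any(cm < 0)) msg <- c(msg, "counts must be nonnegative")
  if (any(cm != round(cm))) msg <- c(msg, "counts must be integers")
  if (length(object@class_labels) != nrow(cm)) {
    msg <- c(msg, "class_labels length must match matrix dimension")
  }
  if (length(msg)) msg else TRUE
})

#' Linear frequency-shift calibration fit
#'
#' Ordinary least-squares fit of frequency shift (Hz) against mass load
#' (ug). The slope is \code{-S_m}; \code{r_squared} is the coefficient of
#' determination.
#'
#' @slot slope numeric(1), Hz/ug.
#' @slot intercept numeric(1), Hz (0 when fitted through the origin).
#' @slot r_squared numeric(1) in [0, 1].
#' @slot n_points integer(1), number of calibration points.
#' @slot through_origin logical(1), whether the intercept was forced to 0.
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  representation(slope = "numeric", intercept = "numeric",
                 r_squared = "numeric", n_points = "integer",
                 through_origin = "logical")
)

setValidity("CalibrationFit", function(object) {
  msg <- character()
  if (object@n_points < 2L) msg <- c(msg, "n_points must be >= 2")
  if (!is.na(object@r_squared) &&
      (object@r_squared < -1e-12 || object@r_squared > 1 + 1e-12)) {
    msg <- c(msg, "r_squared must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

# ---- model configuration classes -------------------------------------------

#' Configuration of the 1-D convolutional classifier
#'
#' The network is input -> [conv - batchnorm - ReLU - maxpool] x n_blocks ->
#' average pool -> dropout -> fully connected -> softmax over
#' \code{n_classes}. Channel width starts at \code{base_channels} and
#' doubles per block up to \code{max_channels}.
#'
#' @slot n_blocks integer(1), number of feature-extraction blocks (>= 1).
#' @slot kernel_size integer(1), convolution kernel length.
#' @slot base_channels integer(1), channels of the first block.
#' @slot max_channels integer(1), cap on channel doubling.
#' @slot pool_size integer(1), max-pool window (= stride).
#' @slot head_pool integer(1), window of the average-pool layer before the
#'   fully connected head.
#' @slot dropout_rate numeric(1) in [0, 1).
#' @slot n_classes integer(1).
#' @exportClass CNNConfig
setClass("CNNConfig",
  representation(n_blocks = "integer", kernel_size = "integer",
                 base_channels = "integer", max_channels = "integer",
                 pool_size = "integer", head_pool = "integer",
                 dropout_rate = "numeric", n_classes = "integer"),
  prototype(n_blocks = 3L, kernel_size = 9L, base_channels = 16L,
            max_channels = 128L, pool_size = 2L, head_pool = 4L,
            dropout_rate = 0.3, n_classes = 10L)
)

setValidity("CNNConfig", function(object) {
  msg <- character()
  if (object@n_blocks < 1L) msg <- c(msg, "n_blocks must be >= 1")
  if (object@kernel_size < 1L) msg <- c(msg, "kernel_size must be >= 1")
  if (object@pool_size < 1L) msg <- c(msg, "pool_size must be >= 1")
  if (object@head_pool < 1L) msg <- c(msg, "head_pool must be >= 1")
  if (object@dropout_rate < 0 || object@dropout_rate >= 1) {
    msg <- c(msg, "dropout_rate must lie in [0, 1)")
  }
  if (object@n_classes < 2L) msg <- c(msg, "n_classes must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Configuration of the LSTM classifier
#'
#' Sequence input -> LSTM(\code{n_units}) -> dropout -> fully connected ->
#' softmax. The architecture sweep of interest varies \code{n_units}
#' (memory blocks, 20--160).
#'
#' @slot n_units integer(1), LSTM memory blocks (hidden width).
#' @slot dropout_rate numeric(1), default 0.2.
#' @slot n_classes integer(1).
#' @exportClass LSTMConfig
setClass("LSTMConfig",
  representation(n_units = "integer", dropout_rate = "numeric",
                 n_classes = "integer"),
  prototype(n_units = 80L, dropout_rate = 0.2, n_classes = 10L)
)

setValidity("LSTMConfig", function(object) {
  msg <- character()
  if (object@n_units < 1L) msg <- c(msg, "n_units must be >= 1")
  if (object@dropout_rate < 0 || object@dropout_rate >= 1) {
    msg <- c(msg, "dropout_rate must lie in [0, 1)")
  }
  if (object@n_classes < 2L) msg <- c(msg, "n_classes must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Configuration of the transformer-encoder classifier
#'
#' Patches of length \code{T} (single channel) are linearly projected to
#' \code{d_model}, a learnable positional encoding is added, \code{L}
#' encoder layers (multi-head self-attention + feed-forward network, each
#' with residual connection and layer normalisation) are applied, the token
#' sequence is globally average-pooled and one fully connected layer with
#' softmax yields the class distribution.
#'
#' @slot L integer(1), encoder depth.
#' @slot d_model integer(1), embedding width (divisible by n_heads).
#' @slot n_heads integer(1).
#' @slot ffn_dim integer(1), feed-forward hidden width.
#' @slot T integer(1), patch length.
#' @slot dropout_rate numeric(1).
#' @slot n_classes integer(1).
#' @exportClass TransformerConfig
setClass("TransformerConfig",
  representation(L = "integer", d_model = "integer", n_heads = "integer",
                 ffn_dim = "integer", T = "integer", dropout_rate = "numeric",
                 n_classes = "integer"),
  prototype(L = 2L, d_model = 64L, n_heads = 4L, ffn_dim = 128L, T = 48L,
            dropout_rate = 0.1, n_classes = 10L)
)

setValidity("TransformerConfig", function(object) {
  msg <- character()
  if (object@L < 1L) msg <- c(msg, "L must be >= 1")
  if (object@d_model %% object@n_heads != 0L) {
    msg <- c(msg, "d_model must be divisible by n_heads")
  }
  if (object@T < 1L) msg <- c(msg, "T must be >= 1")
  if (object@dropout_rate < 0 || object@dropout_rate >= 1) {
    msg <- c(msg, "dropout_rate must lie in [0, 1)")
  }
  if (object@n_classes < 2L) msg <- c(msg, "n_classes must be >= 2")
  if (length(msg)) msg else TRUE
})

#' A built (possibly trained) classifier
#'
#' Holds the architecture family, its configuration object, the layer list
#' with parameters, and run metadata (init seed, input shape, training
#' history once trained).
#'
#' @slot arch character(1), "cnn", "lstm" or "transformer".
#' @slot config one of the *Config classes.
#' @slot layers list of layer objects (internal representation).
#' @slot input_shape integer vector describing the expected input.
#' @slot meta list, seed / history / provenance.
#' @exportClass ClassifierModel
setClass("ClassifierModel",
  representation(arch = "character", config = "ANY", layers = "list",
                 input_shape = "integer", meta = "list")
)
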