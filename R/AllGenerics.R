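#' @include AllClasses.R
NULL

#' Number of trainable parameters of a model
#'
#' @param object a \linkS4class{ClassifierModel}.
#' @return integer scalar.
#' @export
setGeneric("countParams", function(object) standardGeneric("countParams"))

#' Class-probability predictions
#'
#' @param object a trained or untrained \linkS4class{ClassifierModel}.
#' @param x a featurised input batch as produced by
#'   \code{\link{featurizeDataset}}.
#' @param ... unused.
#' @return numeric matrix, batch x n_classes, rows summing to 1.
#' @export
setGeneric("predictProb", function(object, x, ...) standardGeneric("predictProb"))

#' Accessors for resonator and dataset objects
#'
#' \code{resonantFrequency} returns the unloaded fundamental resonance (Hz);
#' \code{qFactor} the quality factor; \code{activeArea} the active area
#' (cm^2, derived from the diameter when only that is set);
#' \code{samplingRate} the audio sampling rate (Hz); \code{massLabels} the
#' per-segment class labels (ug); \code{splitOf} the per-segment split
#' assignment.
#'
#' @param object a \linkS4class{ResonatorSpec} or
#'   \linkS4class{AcousticDataset}.
#' @return numeric or character vector as described.
#' @name accessors
#' @export
setGeneric("resonantFrequency", function(object) standardGeneric("resonantFrequency"))

#' @rdname accessors
#' @export
setGeneric("qFactor", function(object) standardGeneric("qFactor"))

#' @rdname accessors
#' @export
setGeneric("activeArea", function(object) standardGeneric("activeArea"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("massLabels", function(object) standardGeneric("massLabels"))

#' @rdname accessors
#' @export
setGeneric("splitOf", function(object) standardGeneric("splitOf"))
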