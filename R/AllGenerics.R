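#' @import methods
NULL

#' Channel labels of an object
#'
#' @param x an \linkS4class{EEGRecording}, \linkS4class{EEGMontage},
#'   \linkS4class{ConnectivityMatrix} or \linkS4class{ThresholdedNetwork}.
#' @return character vector of channel labels, in recording order.
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Number of channels
#' @param x an object with channels.
#' @return integer scalar.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Sampling rate in Hz
#' @param x an \linkS4class{EEGRecording}.
#' @return numeric scalar (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Signal matrix (channels x samples)
#' @param x an \linkS4class{EEGRecording}.
#' @return numeric matrix, one row per channel.
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' Region map of a montage
#' @param x an \linkS4class{EEGMontage}.
#' @return named list of character vectors (region -> channel labels).
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' Channel indices of a named region
#'
#' @param x an \linkS4class{EEGMontage}.
#' @param region one of the ten region names of the montage.
#' @return integer vector of channel indices in recording order.
#' @export
setGeneric("regionMask", function(x, region) standardGeneric("regionMask"))

#' Connection weights
#' @param x a \linkS4class{ConnectivityMatrix} or
#'   \linkS4class{ThresholdedNetwork}.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
setGeneric("weights", function(x) standardGeneric("weights"))

#' Frequency band of an object
#' @param x an object carrying a band tag.
#' @return character scalar: "theta", "alpha" or "beta".
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))

#' Connectivity estimator used
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return character scalar: "paper_formula" or "standard_wpli".
#' @export
setGeneric("estimator", function(x) standardGeneric("estimator"))

#' Retained edge proportion of a thresholded network
#' @param x a \linkS4class{ThresholdedNetwork}.
#' @return numeric scalar in (0, 1].
#' @export
setGeneric("proportion", function(x) standardGeneric("proportion"))
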