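#' EEGMontage: channel layout and region groupings
#'
#' Holds the ordered 56-channel label list and the ten named scalp regions
#' used for local-metric aggregation. Channels not listed in any region table
#' but required to reach 56 are recorded in \code{inferred}.
#'
#' @slot channels character(56), unique channel labels in recording order.
#' @slot regions named list of character vectors, region -> channel labels.
#' @slot inferred character, labels present in \code{channels} whose identity
#'   is inferred rather than tabulated.
#' @aliases EEGMontage
#' @exportClass EEGMontage
setClass("EEGMontage",
  representation(channels = "character", regions = "list",
                 inferred = "character"))

setValidity("EEGMontage", function(object) {
  msg <- character()
  if (length(object@channels) != 56L)
    msg <- c(msg, "montage must have exactly 56 channels")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  bad <- setdiff(unlist(object@regions), object@channels)
  if (length(bad))
    msg <- c(msg, paste("region channels not in channel list:",
                        paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' EEGRecording: one subject-condition multichannel EEG
#'
#' @slot signals numeric matrix, channels x samples; rownames are the channel
#'   labels.
#' @slot fs sampling rate in Hz.
#' @slot subject subject identifier.
#' @slot condition "pre" or "post".
#' @aliases EEGRecording-class
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(signals = "matrix", fs = "numeric", subject = "character",
                 condition = "character"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signals))
    msg <- c(msg, "signals must be a numeric matrix")
  if (is.null(rownames(object@signals)))
    msg <- c(msg, "signals must have channel labels as rownames")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (!object@condition %in% c("pre", "post"))
    msg <- c(msg, "condition must be 'pre' or 'post'")
  if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{EEGRecording}
#'
#' @param signals channels x samples numeric matrix with rownames.
#' @param fs sampling rate (Hz).
#' @param subject subject identifier.
#' @param condition "pre" or "post".
#' @return an \linkS4class{EEGRecording}.
#' @export
EEGRecording <- function(signals, fs, subject = "s1", condition = "pre") {
  new("EEGRecording", signals = signals, fs = as.numeric(fs),
      subject = as.character(subject), condition = condition)
}

#' ConnectivityMatrix: symmetric wPLI weights for one band
#'
#' @slot weights symmetric numeric matrix in [0,1] with zero diagonal;
#'   dimnames are channel labels.
#' @slot band "theta", "alpha" or "beta".
#' @slot estimator "paper_formula" (magnitude of the time-averaged sine of
#'   the phase difference) or "standard_wpli" (imaginary-part-weighted index).
#' @aliases ConnectivityMatrix-class
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(weights = "matrix", band = "character",
                 estimator = "character"))

setValidity("ConnectivityMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10)))
    msg <- c(msg, "weights must be symmetric")
  if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be exactly 0")
  if (any(w < 0 | w > 1)) msg <- c(msg, "weights must lie in [0,1]")
  if (!object@estimator %in% c("paper_formula", "standard_wpli"))
    msg <- c(msg, "unknown estimator")
  if (length(msg)) msg else TRUE
})

#' ThresholdedNetwork: proportionally thresholded connectivity
#'
#' Retains the globally strongest fraction of edges of a
#' \linkS4class{ConnectivityMatrix}; discarded entries are zero, retained
#' weights are unchanged (not binarized).
#'
#' @slot weights symmetric numeric matrix, non-retained entries zero.
#' @slot proportion fraction of the n(n-1)/2 possible edges retained.
#' @aliases ThresholdedNetwork-class
#' @exportClass ThresholdedNetwork
setClass("ThresholdedNetwork",
  representation(weights = "matrix", proportion = "numeric"))

setValidity("ThresholdedNetwork", function(object) {
  w <- object@weights
  msg <- character()
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10)))
    msg <- c(msg, "weights must be symmetric")
  if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be 0")
  if (object@proportion <= 0 || object@proportion > 1)
    msg <- c(msg, "proportion must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: ground-truth parameters for a synthetic cohort
#'
#' @slot nSubjects number of subjects (each simulated pre and post).
#' @slot fs sampling rate in Hz.
#' @slot duration record length in seconds; \code{duration * fs} must be a
#'   whole number of samples.
#' @slot bandPower named list band -> c(pre, post) oscillator variance in
#'   linear units.
#' @slot couplingSpec list of coupling cluster entries (see
#'   \code{\link{defaultCouplingSpec}}).
#' @slot noiseExponent spectral slope beta of the 1/f^beta background.
#' @slot noiseVariance variance of the background noise per channel.
#' @slot subjectGainSD between-subject SD of the common log10 power gain.
#' @slot bandJitterSD within-subject per-band, per-condition log10 power
#'   jitter SD.
#' @slot couplingJitterSD SD of the per-subject-condition multiplicative
#'   jitter applied to each cluster's coupling strength.
#' @slot amplitudeJitter half-width of the uniform per-channel amplitude
#'   scaling (0.2 means +/-20\%).
#' @slot vasf named list with elements \code{fatigue} and \code{energy}, each
#'   a list with c(mean, sd) for \code{pre} and \code{post} on the 0-100
#'   scale.
#' @slot montage the \linkS4class{EEGMontage} channels are drawn from.
#' @slot seed integer root seed; identical seed implies a bit-identical
#'   cohort.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nSubjects = "numeric", fs = "numeric", duration = "numeric",
                 bandPower = "list", couplingSpec = "list",
                 noiseExponent = "numeric", noiseVariance = "numeric",
                 subjectGainSD = "numeric", bandJitterSD = "numeric",
                 couplingJitterSD = "numeric", amplitudeJitter = "numeric",
                 vasf = "list", montage = "EEGMontage", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be >= 1")
  if (object@fs <= 0 || object@duration <= 0)
    msg <- c(msg, "fs and duration must be positive")
  n <- object@fs * object@duration
  if (abs(n - round(n)) > 1e-8)
    msg <- c(msg, "duration * fs must be an integer sample count")
  for (b in names(object@bandPower)) {
    if (!b %in% c("theta", "alpha", "beta"))
      msg <- c(msg, paste("unknown band in bandPower:", b))
    if (any(object@bandPower[[b]] < 0))
      msg <- c(msg, "band power levels must be non-negative")
  }
  for (cs in object@couplingSpec) {
    bad <- setdiff(cs$channels, object@montage@channels)
    if (length(bad))
      msg <- c(msg, paste("unknown channel in couplingSpec:",
                          paste(bad, collapse = ", ")))
    s <- unlist(cs$strength)
    if (any(s < 0 | s > 1))
      msg <- c(msg, "coupling strength must lie in [0,1]")
    if (!is.null(cs$lagStep) && (cs$lagStep <= -pi || cs$lagStep > pi))
      msg <- c(msg, "phase lag must lie in (-pi, pi]")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: paired recordings with retained ground truth
#'
#' @slot recordings list of \linkS4class{EEGRecording}, named
#'   "<subject>_<condition>".
#' @slot truth the \linkS4class{SimulationConfig} that produced the cohort.
#' @slot vasf data.frame with columns subject, condition, fatigue, energy.
#' @aliases SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(recordings = "list", truth = "SimulationConfig",
                 vasf = "data.frame"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  nch <- vapply(object@recordings, function(r) nrow(r@signals), integer(1))
  if (length(nch) && any(nch != 56L))
    msg <- c(msg, "every recording must have the montage's 56 channels")
  if (length(msg)) msg else TRUE
})

#' @describeIn EEGRecording channel labels
#' @export
setMethod("channels", "EEGRecording", function(x) rownames(x@signals))

#' @describeIn EEGMontage channel labels in recording order
#' @export
setMethod("channels", "EEGMontage", function(x) x@channels)

setMethod("channels", "ConnectivityMatrix", function(x) rownames(x@weights))
setMethod("channels", "ThresholdedNetwork", function(x) rownames(x@weights))

#' @describeIn EEGRecording number of channels
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@signals))
setMethod("nChannels", "EEGMontage", function(x) length(x@channels))

#' @describeIn EEGRecording sampling rate (Hz)
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @describeIn EEGRecording channels x samples signal matrix
#' @export
setMethod("signals", "EEGRecording", function(x) x@signals)

#' @describeIn EEGMontage named region -> channel list
#' @export
setMethod("regions", "EEGMontage", function(x) x@regions)

setMethod("weights", "ConnectivityMatrix", function(x) x@weights)
setMethod("weights", "ThresholdedNetwork", function(x) x@weights)
setMethod("bandName", "ConnectivityMatrix", function(x) x@band)
setMethod("estimator", "ConnectivityMatrix", function(x) x@estimator)
setMethod("proportion", "ThresholdedNetwork", function(x) x@proportion)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: subject %s, %s condition\n  %d channels x %d samples @ %g Hz (%.1f s)\n",
      object@subject, object@condition, nrow(object@signals),
      ncol(object@signals), object@fs, ncol(object@signals) / object@fs))
})

setMethod("show", "EEGMontage", function(object) {
  cat(sprintf("EEGMontage: %d channels, %d regions\n",
      length(object@channels), length(object@regions)))
  for (r in names(object@regions))
    cat(sprintf("  %-18s %s\n", r, paste(object@regions[[r]], collapse = " ")))
  if (length(object@inferred))
    cat("  inferred (not tabulated):", paste(object@inferred, collapse = " "),
        "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  w <- object@weights[upper.tri(object@weights)]
  cat(sprintf("ConnectivityMatrix: %d x %d, band %s, estimator %s\n  weights: median %.3f, max %.3f\n",
      nrow(object@weights), ncol(object@weights), object@band,
      object@estimator, stats::median(w), max(w)))
})

setMethod("show", "ThresholdedNetwork", function(object) {
  cat(sprintf("ThresholdedNetwork: %d nodes, proportion %.2f (%d edges retained)\n",
      nrow(object@weights), object@proportion,
      sum(object@weights[upper.tri(object@weights)] > 0)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects x 2 conditions (%d recordings), seed %d\n",
      object@truth@nSubjects, length(object@recordings),
      as.integer(object@truth@seed)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d subjects, %g Hz, %g s, seed %d\n  bands: %s\n  coupling clusters: %d\n",
      as.integer(object@nSubjects), object@fs, object@duration,
      as.integer(object@seed),
      paste(names(object@bandPower), collapse = ", "),
      length(object@couplingSpec)))
})
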