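## Band-pass filtering, Hilbert instantaneous phase, and weighted phase lag
## index (wPLI) connectivity.
##
## Two estimators ship. "paper_formula" is the study's printed definition,
## the magnitude of the time-averaged sine of the instantaneous phase
## difference, |mean_k sin(dphi_k)|. "standard_wpli" is the conventional
## imaginary-part-weighted index of the cross-spectrum,
## |mean Im(X)| / mean |Im(X)| with X_k = z_i(k) * conj(z_j(k)). The two
## coincide on unit-amplitude analytic signals only in the numerator; both
## are bounded in [0, 1] and both suppress strictly zero-lag coupling.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase distortion).
#' One second of edge samples at each end is flagged for exclusion from
#' phase statistics via the \code{"edgeSamples"} attribute.
#'
#' @param x numeric vector, or channels x samples matrix (filtered row-wise).
#' @param band c(lo, hi) in Hz or a band name from \code{\link{eegBands}}.
#' @param fs sampling rate, Hz.
#' @return filtered signal of the same shape, with attribute
#'   \code{edgeSamples} = number of transient samples to drop at each end.
#' @export
bandpassFilter <- function(x, band, fs) {
  if (is.character(band)) band <- eegBands()[[match.arg(band,
                                             names(eegBands()))]]
  if (band[2] >= fs / 2) stop("band extends to or beyond the Nyquist frequency")
  if (band[1] <= 0) stop("band lo must be positive")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  out <- if (is.matrix(x)) {
    t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  } else {
    signal::filtfilt(bf, x)
  }
  if (is.matrix(x)) dimnames(out) <- dimnames(x)
  attr(out, "edgeSamples") <- as.integer(fs)
  out
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal (frequency-domain Hilbert construction) per
#' sample, in (-pi, pi].
#'
#' @param x numeric vector (band-limited), or channels x samples matrix.
#' @return phase series of the same shape, radians.
#' @export
instantaneousPhase <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(row) Arg(.analyticSignal(row))))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  Arg(.analyticSignal(x))
}

#' wPLI between two phase (or analytic) series
#'
#' @param phaseI,phaseJ instantaneous phase vectors, radians, equal length.
#' @param estimator "paper_formula" (default): |mean sin(phaseI - phaseJ)|;
#'   "standard_wpli": |mean Im(X)| / mean |Im(X)| with
#'   X = ampI * ampJ * exp(1i * (phaseI - phaseJ)).
#' @param ampI,ampJ optional amplitude envelopes for the standard estimator
#'   (default 1, i.e. phase-only weighting).
#' @return weight in [0, 1]; the standard estimator returns 0 when the
#'   imaginary cross-spectrum is identically zero.
#' @examples
#' phi <- runif(1000, -pi, pi)
#' wpliPair(phi + pi/2, phi)   # constant lag pi/2 -> 1
#' @export
wpliPair <- function(phaseI, phaseJ,
                     estimator = c("paper_formula", "standard_wpli"),
                     ampI = NULL, ampJ = NULL) {
  estimator <- match.arg(estimator)
  if (length(phaseI) != length(phaseJ)) stop("phase series length mismatch")
  if (length(phaseI) < 2L) stop("need at least 2 samples")
  d <- sin(phaseI - phaseJ)
  if (estimator == "paper_formula") return(abs(mean(d)))
  if (!is.null(ampI)) d <- d * ampI
  if (!is.null(ampJ)) d <- d * ampJ
  den <- mean(abs(d))
  if (den == 0) return(0)
  min(abs(mean(d)) / den, 1)
}

#' wPLI connectivity matrix of a recording
#'
#' Band-pass filters every channel, takes the Hilbert instantaneous phase,
#' drops one second of filter edge transients at each end, and computes the
#' wPLI for all unique channel pairs over the remaining continuous record.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param band band name or c(lo, hi) Hz (default "alpha").
#' @param estimator "paper_formula" (default) or "standard_wpli".
#' @param montage optional \linkS4class{EEGMontage}; when supplied, the
#'   recording must contain all its channels and rows are ordered to match.
#' @return a \linkS4class{ConnectivityMatrix} (symmetric, zero diagonal,
#'   entries in [0, 1]).
#' @export
connectivityMatrix <- function(recording, band = "alpha",
                               estimator = c("paper_formula",
                                             "standard_wpli"),
                               montage = NULL) {
  estimator <- match.arg(estimator)
  bandTag <- if (is.character(band)) band else "custom"
  sig <- signals(recording)
  if (!is.null(montage)) {
    missing <- setdiff(montage@channels, rownames(sig))
    if (length(missing))
      stop("recording is missing montage channels: ",
           paste(missing, collapse = ", "))
    sig <- sig[montage@channels, , drop = FALSE]
  }
  if (nrow(sig) < 2L) stop("need at least two channels")
  fs <- samplingRate(recording)
  filt <- bandpassFilter(sig, band, fs)
  edge <- attr(filt, "edgeSamples")
  n <- ncol(filt)
  if (n <= 2L * edge + 1L) stop("recording too short after edge trimming")
  keep <- (edge + 1L):(n - edge)

  Z <- t(apply(filt, 1, .analyticSignal))[, keep, drop = FALSE]
  N <- ncol(Z)
  if (estimator == "paper_formula") {
    U <- Z / abs(Z)                       # unit phasors exp(1i * phase)
    S <- (U %*% Conj(t(U))) / N
    W <- abs(Im(S))
  } else {
    A <- Re(Z); B <- Im(Z)
    nCh <- nrow(Z)
    num <- (B %*% t(A) - A %*% t(B)) / N  # mean Im(z_i conj(z_j))
    W <- matrix(0, nCh, nCh)
    for (i in seq_len(nCh - 1L)) {
      for (j in (i + 1L):nCh) {
        v <- B[i, ] * A[j, ] - A[i, ] * B[j, ]
        den <- mean(abs(v))
        W[i, j] <- W[j, i] <- if (den == 0) 0 else abs(num[i, j]) / den
      }
    }
  }
  W <- (W + t(W)) / 2                     # enforce exact symmetry
  W <- .clamp(W, 0, 1)
  diag(W) <- 0
  dimnames(W) <- list(rownames(sig), rownames(sig))
  new("ConnectivityMatrix", weights = W, band = bandTag,
      estimator = estimator)
}
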