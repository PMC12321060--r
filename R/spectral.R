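## Welch power spectral density and band-power extraction.

#' Canonical EEG frequency bands
#'
#' @return named list: theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30)
#'   (Hz). Band membership downstream is half-open, [lo, hi), so a shared
#'   edge belongs to the upper band only.
#' @export
eegBands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hanning-tapered, mean-detrended, overlapping
#' segments; one-sided density scaled so that the integral over frequency
#' equals the signal variance (Parseval).
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate, Hz.
#' @param segmentLength samples per segment (default \code{round(2 * fs)},
#'   i.e. 2 s, giving 0.5 Hz resolution).
#' @param overlap fraction of segment overlap in [0, 1) (default 0.5).
#' @return list with \code{freq} (Hz), \code{psd} (density, unit^2/Hz),
#'   \code{df} (frequency resolution, Hz) and \code{nSegments}.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1/500))
#' sp <- welchPsd(x, 500)
#' sp$freq[which.max(sp$psd)]   # 10 Hz
#' @export
welchPsd <- function(x, fs, segmentLength = round(2 * fs), overlap = 0.5) {
  if (!all(is.finite(x))) stop("non-finite samples in input signal")
  n <- length(x)
  L <- as.integer(segmentLength)
  if (L > n) stop("signal shorter than one segment")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  hop <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))   # periodic Hanning
  scale <- 1 / (fs * sum(w^2))
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 * scale
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  ## one-sided: double everything except DC and (for even L) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2L == 0L) dbl[nf] <- 1
  psd <- psd * dbl
  df <- fs / L
  list(freq = (seq_len(nf) - 1) * df, psd = psd, df = df,
       nSegments = length(starts))
}

#' Band power from a Welch spectrum
#'
#' Integrates the density over the half-open interval [lo, hi) and, by
#' default, returns the log10 of that integral (the scale on which the
#' pipeline's band powers are compared).
#'
#' @param spectrum output of \code{\link{welchPsd}}.
#' @param band c(lo, hi) in Hz, or a band name from \code{\link{eegBands}}.
#' @param log10 return log10-transformed power (default TRUE).
#' @return numeric scalar; \code{-Inf} for an all-zero band when
#'   \code{log10 = TRUE}.
#' @export
bandPower <- function(spectrum, band, log10 = TRUE) {
  if (is.character(band)) band <- eegBands()[[match.arg(band,
                                             names(eegBands()))]]
  nyq <- max(spectrum$freq)
  if (band[2] > nyq + 1e-9) stop("band extends beyond the Nyquist frequency")
  if (band[1] >= band[2]) stop("band lo must be below hi")
  idx <- spectrum$freq >= band[1] & spectrum$freq < band[2]
  p <- sum(spectrum$psd[idx]) * spectrum$df
  if (log10) base::log10(p) else p
}

#' BandSpectrum: per-channel and whole-brain band powers of one recording
#'
#' @slot perChannel numeric matrix, channels x bands, log10 band power.
#' @slot wholeBrainMean named numeric, per-band arithmetic mean of the
#'   per-channel log10 powers over all channels.
#' @slot resolution frequency resolution of the underlying spectrum (Hz).
#' @aliases BandSpectrum-class
#' @exportClass BandSpectrum
setClass("BandSpectrum",
  representation(perChannel = "matrix", wholeBrainMean = "numeric",
                 resolution = "numeric"))

setValidity("BandSpectrum", function(object) {
  wb <- colMeans(object@perChannel)
  if (!isTRUE(all.equal(unname(wb), unname(object@wholeBrainMean),
                        tolerance = 1e-10)))
    return("wholeBrainMean must equal the channel-wise mean of perChannel")
  TRUE
})

setMethod("show", "BandSpectrum", function(object) {
  cat(sprintf("BandSpectrum: %d channels, resolution %.3g Hz\n",
              nrow(object@perChannel), object@resolution))
  print(round(object@wholeBrainMean, 3))
})

#' Band powers of a recording
#'
#' Welch PSD per channel, band powers (log10) for each requested band, and
#' the whole-brain (channel-wise) mean per band.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param bands named list of c(lo, hi) bands (default \code{eegBands()}).
#' @param segmentLength,overlap passed to \code{\link{welchPsd}}.
#' @return a \linkS4class{BandSpectrum}.
#' @export
bandSpectrum <- function(recording, bands = eegBands(),
                         segmentLength = round(2 * samplingRate(recording)),
                         overlap = 0.5) {
  sig <- signals(recording)
  fs <- samplingRate(recording)
  pc <- matrix(NA_real_, nrow = nrow(sig), ncol = length(bands),
               dimnames = list(rownames(sig), names(bands)))
  for (i in seq_len(nrow(sig))) {
    sp <- welchPsd(sig[i, ], fs, segmentLength, overlap)
    for (b in names(bands)) pc[i, b] <- bandPower(sp, bands[[b]])
  }
  new("BandSpectrum", perChannel = pc, wholeBrainMean = colMeans(pc),
      resolution = fs / segmentLength)
}

#' Whole-brain band-power table for a cohort
#'
#' One row per subject, condition and band, holding the whole-brain mean
#' log10 band power. This is the table the statistics layer consumes.
#'
#' @param cohort a \linkS4class{SyntheticCohort}, or a plain list of
#'   \linkS4class{EEGRecording}s.
#' @param bands named list of bands (default \code{eegBands()}).
#' @param segmentLength,overlap passed to \code{\link{welchPsd}}; the default
#'   segment is 2 s of the (shared) sampling rate.
#' @return data.frame with columns subject, condition, band, value.
#' @export
cohortBandTable <- function(cohort, bands = eegBands(),
                            segmentLength = NULL, overlap = 0.5) {
  recs <- if (is(cohort, "SyntheticCohort")) cohort@recordings else cohort
  fs <- unique(vapply(recs, samplingRate, numeric(1)))
  if (length(fs) != 1L) stop("all recordings must share one sampling rate")
  chs <- lapply(recs, channels)
  if (length(unique(vapply(chs, paste, character(1), collapse = ","))) != 1L)
    stop("all recordings must share one montage (same channels, same order)")
  if (is.null(segmentLength)) segmentLength <- round(2 * fs)
  rows <- lapply(recs, function(r) {
    bs <- bandSpectrum(r, bands, segmentLength, overlap)
    data.frame(subject = r@subject, condition = r@condition,
               band = names(bands),
               value = unname(bs@wholeBrainMean[names(bands)]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
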