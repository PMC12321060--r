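## FFT-based signal primitives shared by the simulator and the connectivity
## module. Kept internal; none of these are part of the module surface.

## Deterministic substream seed from a root seed plus integer tags.
## All arithmetic stays below 2^53 so the result is exact in doubles.
.deriveSeed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) h <- (h * 48271 + as.double(t) * 9973 + 1) %% 2147483647
  as.integer(h)
}

## Analytic signal via the frequency-domain Hilbert construction:
## zero out negative frequencies, double positive ones.
.analyticSignal <- function(x) {
  if (!all(is.finite(x))) stop("non-finite samples in input signal")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

## Constant phase shift of a (band-limited) real signal: rotate its analytic
## representation by -phi, so the shifted copy LAGS the original by phi
## (phase(original) - phase(shifted) = phi).
.phaseShift <- function(x, phi) {
  Re(.analyticSignal(x) * exp(-1i * phi))
}

## 1/f^beta Gaussian background noise, unit variance. Spectral shaping of
## white Gaussian noise: amplitude ~ f^(-beta/2), DC removed.
.pinkNoise <- function(n, exponent = 1.0) {
  if (n < 2) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                 # avoid the DC singularity
  f <- pmin(f, n - f + 1)                   # mirror for negative frequencies
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

## Narrow-band Gaussian carrier: white noise filtered in the frequency
## domain with a flat pass band and raised-cosine edges (zero-phase,
## circular, so no edge transients); unit variance. The instantaneous phase
## of such a carrier is nondegenerate, unlike a pure sinusoid's.
.bandlimitedNoise <- function(n, fs, band, rolloff = 0.5) {
  rolloff <- min(rolloff, (band[2] - band[1]) / 4)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  lo <- band[1] + rolloff                  # transition bands sit INSIDE the
  hi <- band[2] - rolloff                  # nominal band edges
  mask <- numeric(n)
  mask[f >= lo & f <= hi] <- 1
  sl <- f >= band[1] & f < lo
  mask[sl] <- 0.5 * (1 + cos(pi * (lo - f[sl]) / rolloff))
  sh <- f > hi & f <= band[2]
  mask[sh] <- 0.5 * (1 + cos(pi * (f[sh] - hi) / rolloff))
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * mask, inverse = TRUE) / n)
  x / stats::sd(x)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
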