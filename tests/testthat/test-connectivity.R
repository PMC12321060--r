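test_that("the band-pass filter keeps in-band and rejects out-of-band tones", {
  fs <- 500
  t <- seq_len(10 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  core <- (2 * fs):(8 * fs)   # away from edges
  yA <- bandpassFilter(x, "alpha", fs)
  expect_gte(sd(yA[core]) / sd(x[core]), 0.95)
  yB <- bandpassFilter(x, "beta", fs)
  expect_lte(sd(yB[core]) / sd(x[core]), 0.10)
  expect_equal(bandpassFilter(numeric(1000), "alpha", fs),
               numeric(1000), ignore_attr = TRUE)
  expect_error(bandpassFilter(x, c(13, 300), fs), "Nyquist")
  expect_identical(attr(yA, "edgeSamples"), as.integer(fs))
})

test_that("instantaneous phase advances at the oscillation frequency", {
  fs <- 500
  t <- seq_len(4 * fs) / fs
  ph <- instantaneousPhase(cos(2 * pi * 10 * t))
  core <- (fs):(3 * fs)
  d <- diff(ph[core])
  d <- (d + pi) %% (2 * pi) - pi          # unwrap steps
  slope <- mean(d) * fs                    # rad/s
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
  expect_true(all(ph >= -pi & ph <= pi))
  # quadrature pair: cos leads sin by pi/2
  ph2 <- instantaneousPhase(sin(2 * pi * 10 * t))
  dphi <- (ph[core] - ph2[core] + pi) %% (2 * pi) - pi
  expect_equal(mean(dphi), pi / 2, tolerance = 0.01)
  expect_error(instantaneousPhase(c(1, NA, 3)), "non-finite")
})

test_that("wpliPair reproduces the analytic constant-lag values", {
  set.seed(1)
  phi <- runif(5000, -pi, pi)
  expect_equal(wpliPair(phi + pi / 2, phi), 1.0, tolerance = 1e-12)
  expect_equal(wpliPair(phi, phi), 0.0, tolerance = 1e-12)
  expect_equal(wpliPair(phi + pi / 6, phi), 0.5, tolerance = 1e-12)
  expect_equal(wpliPair(phi + pi / 4, phi), sin(pi / 4), tolerance = 1e-12)
  # antisymmetric lag: same weight both directions
  expect_equal(wpliPair(phi, phi + pi / 6), wpliPair(phi + pi / 6, phi))
  expect_error(wpliPair(phi, phi[-1]), "mismatch")
})

test_that("independent phases stay below the null bound", {
  set.seed(2)
  a <- runif(1e4, -pi, pi)
  b <- runif(1e4, -pi, pi)
  expect_lte(wpliPair(a, b), 0.05)
  expect_lte(wpliPair(a, b, estimator = "standard_wpli"), 0.05)
})

test_that("the estimator spread shrinks as the sample count grows", {
  set.seed(3)
  spread <- vapply(c(500, 5000, 50000), function(N) {
    sd(replicate(20, wpliPair(runif(N, -pi, pi), runif(N, -pi, pi))))
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("wpliPair is invariant to a common time shift of both channels", {
  set.seed(4)
  phi <- runif(3000, -pi, pi)
  psi <- phi + rnorm(3000, pi / 4, 0.3)
  k <- 137
  roll <- function(x) c(x[-seq_len(k)], x[seq_len(k)])
  expect_equal(wpliPair(roll(phi), roll(psi)), wpliPair(phi, psi))
})

test_that("connectivity matrices are symmetric, zero-diagonal and bounded", {
  cfg <- coupledPairConfig(pi / 2, duration = 20, seed = 21)
  rec <- simulateRecording(cfg, 1, "pre")
  for (est in c("paper_formula", "standard_wpli")) {
    cm <- connectivityMatrix(rec, "alpha", estimator = est,
                             montage = defaultMontage())
    w <- weights(cm)
    expect_identical(dim(w), c(56L, 56L))
    expect_equal(w, t(w))
    expect_true(all(diag(w) == 0))
    expect_true(all(w >= 0 & w <= 1))
    expect_gte(w["C3", "C4"], 0.9)   # the injected fully coupled pair
  }
})

test_that("amplitude rescaling of a channel leaves the matrix unchanged", {
  cfg <- coupledPairConfig(pi / 3, strength = 0.7, duration = 10, seed = 22)
  rec <- simulateRecording(cfg, 1, "pre")
  sig <- signals(rec)[c("C3", "C4", "CZ", "PZ"), ]
  w1 <- weights(connectivityMatrix(EEGRecording(sig, 500), "alpha"))
  sig2 <- sig
  sig2["C3", ] <- 10 * sig2["C3", ]
  w2 <- weights(connectivityMatrix(EEGRecording(sig2, 500), "alpha"))
  expect_equal(w1, w2, tolerance = 1e-6)
})

test_that("a montage mismatch is reported", {
  set.seed(5)
  sig <- matrix(rnorm(4 * 3000), nrow = 4,
                dimnames = list(c("C3", "C4", "CZ", "PZ"), NULL))
  expect_error(connectivityMatrix(EEGRecording(sig, 500), "alpha",
                                  montage = defaultMontage()),
               "missing montage channels")
})
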