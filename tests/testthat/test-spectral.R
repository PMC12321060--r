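test_that("Welch density integrates to the variance (Parseval)", {
  set.seed(1)
  x <- rnorm(5e4)
  sp <- welchPsd(x, 500)
  expect_equal(sum(sp$psd) * sp$df, var(x), tolerance = 0.05)
})

test_that("a pure sinusoid peaks within one bin of its frequency", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq_len(10 * fs) / fs)
  sp <- welchPsd(x, fs)
  expect_lte(abs(sp$freq[which.max(sp$psd)] - 10), sp$df)
})

test_that("degenerate and invalid inputs are handled", {
  expect_equal(welchPsd(numeric(1000), 500)$psd, numeric(501))
  expect_error(welchPsd(rnorm(100), 500, segmentLength = 1000), "shorter")
  expect_error(welchPsd(c(rnorm(999), NA), 500), "non-finite")
  expect_error(welchPsd(rnorm(2000), 500, overlap = 1), "overlap")
  sp <- welchPsd(rnorm(2000), 100)
  expect_error(bandPower(sp, c(13, 60)), "Nyquist")
})

test_that("band power separates a sinusoid's band by >= 20 dB", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq_len(20 * fs) / fs)
  sp <- welchPsd(x, fs)
  a <- bandPower(sp, "alpha")
  expect_gte(a - bandPower(sp, "theta"), 2)   # log10 units: 20 dB
  expect_gte(a - bandPower(sp, "beta"), 2)
})

test_that("white-noise band powers scale with bandwidth before the log", {
  set.seed(2)
  sp <- welchPsd(rnorm(2e5), 500)
  th <- bandPower(sp, "theta", log10 = FALSE)   # 4 Hz wide
  al <- bandPower(sp, "alpha", log10 = FALSE)   # 5 Hz wide
  be <- bandPower(sp, "beta", log10 = FALSE)    # 17 Hz wide
  expect_equal(al / th, 5 / 4, tolerance = 0.1)
  expect_equal(be / th, 17 / 4, tolerance = 0.1)
})

test_that("doubling the amplitude adds log10(4) to every band power", {
  set.seed(3)
  x <- rnorm(1e4)
  sp1 <- welchPsd(x, 500)
  sp2 <- welchPsd(2 * x, 500)
  for (b in names(eegBands()))
    expect_equal(bandPower(sp2, b) - bandPower(sp1, b), log10(4),
                 tolerance = 1e-10)
})

test_that("the Welch estimator variance shrinks with more segments", {
  set.seed(4)
  spread <- vapply(c(4, 8, 16), function(nseg) {
    ests <- replicate(40, {
      x <- rnorm(nseg * 250)
      sp <- welchPsd(x, 500, segmentLength = 500, overlap = 0.5)
      bandPower(sp, "alpha", log10 = FALSE)
    })
    var(ests)
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("whole-brain means equal channel means and ignore channel order", {
  set.seed(5)
  sig <- matrix(rnorm(8 * 4000), nrow = 8,
                dimnames = list(paste0("ch", 1:8), NULL))
  rec <- EEGRecording(sig, fs = 500)
  bs <- bandSpectrum(rec)
  expect_equal(unname(bs@wholeBrainMean), unname(colMeans(bs@perChannel)))
  perm <- sample(8)
  rec2 <- EEGRecording(sig[perm, ], fs = 500)
  expect_equal(bandSpectrum(rec2)@wholeBrainMean, bs@wholeBrainMean)
})

test_that("cohort band table has one row per subject, condition and band", {
  cfg <- simulationConfig(nSubjects = 2, duration = 4, seed = 9)
  tab <- cohortBandTable(simulateCohort(cfg))
  expect_identical(nrow(tab), 12L)   # 2 subjects x 2 conditions x 3 bands
  expect_setequal(unique(tab$band), c("theta", "alpha", "beta"))
  # mismatched sampling rates are rejected
  r1 <- simulateRecording(cfg, 1, "pre")
  r2 <- EEGRecording(signals(r1), fs = 250)
  expect_error(cohortBandTable(list(r1, r2)), "sampling rate")
})
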