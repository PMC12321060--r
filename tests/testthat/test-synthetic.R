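test_that("identical seeds give bit-identical cohorts", {
  cfg <- simulationConfig(nSubjects = 2, duration = 4, seed = 7)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(lapply(a@recordings, signals),
                   lapply(b@recordings, signals))
  expect_identical(a@vasf, b@vasf)
  # and a recording simulated standalone matches its in-cohort twin
  solo <- simulateRecording(cfg, 2, "post")
  expect_identical(signals(solo), signals(a@recordings[["s02_post"]]))
})

test_that("cohort counts and VAS-F separation match the configuration", {
  cfg <- simulationConfig(nSubjects = 3, duration = 2, seed = 1)
  coh <- simulateCohort(cfg)
  expect_length(coh@recordings, 6L)
  expect_identical(nrow(coh@vasf), 6L)
  expect_true(all(vapply(coh@recordings,
                         function(r) nrow(signals(r)), integer(1)) == 56L))
  # default separation (means 11 vs 81): paired fatigue difference sign
  # uniform across subjects
  cfg2 <- simulationConfig(nSubjects = 12, duration = 2, seed = 5)
  v <- simulateCohort(cfg2)@vasf
  pre <- v$fatigue[v$condition == "pre"][order(v$subject[v$condition == "pre"])]
  post <- v$fatigue[v$condition == "post"][order(v$subject[v$condition == "post"])]
  expect_true(all(post > pre))
})

test_that("configuration errors are caught", {
  expect_error(simulationConfig(nSubjects = 0), "nSubjects")
  expect_error(simulationConfig(duration = -1), "positive")
  expect_error(simulationConfig(duration = 1.0001), "integer sample count")
  expect_error(
    simulationConfig(couplingSpec = list(list(
      channels = c("C3", "NOPE"), band = "alpha", lagStep = 0.9,
      strength = c(pre = 0.5, post = 0.5), masterMix = c(pre = 0, post = 0),
      masterLag = 0))),
    "unknown channel")
  expect_error(
    simulationConfig(couplingSpec = list(list(
      channels = c("C3", "C4"), band = "alpha", lagStep = 0.9,
      strength = c(pre = 1.5, post = 0.5), masterMix = c(pre = 0, post = 0),
      masterLag = 0))),
    "strength")
})

test_that("alpha-band energy is concentrated where it belongs", {
  # a noise-free 10 Hz sinusoid: >= 99% of Welch power inside 8-13 Hz
  fs <- 500
  x <- sin(2 * pi * 10 * seq_len(20 * fs) / fs)
  sp <- welchPsd(x, fs)
  expect_gt(bandPower(sp, c(8, 13), log10 = FALSE) / (sum(sp$psd) * sp$df),
            0.99)
  # the generator's narrow-band alpha oscillator: >= 95% in-band (its
  # raised-cosine skirts sit inside the nominal edges, minus bin leakage)
  cfg <- simulationConfig(nSubjects = 1, duration = 20, seed = 3,
                          bandPower = list(alpha = c(pre = 1, post = 1)),
                          couplingSpec = list(), noiseVariance = 0,
                          subjectGainSD = 0, bandJitterSD = 0,
                          amplitudeJitter = 0)
  rec <- simulateRecording(cfg, 1, "pre")
  sp2 <- welchPsd(signals(rec)[1, ], samplingRate(rec))
  expect_gt(bandPower(sp2, c(8, 13), log10 = FALSE) / (sum(sp2$psd) * sp2$df),
            0.95)
})

test_that("coupled-pair wPLI converges to |sin(lag)| of the injected lag", {
  for (lag in c(pi / 6, pi / 4, pi / 2)) {
    cfg <- coupledPairConfig(lag, duration = 30, seed = 11)
    rec <- simulateRecording(cfg, 1, "pre")
    cm <- connectivityMatrix(rec, "alpha")
    expect_equal(weights(cm)["C3", "C4"], abs(sin(lag)), tolerance = 0.05)
  }
})

test_that("uncoupled channels stay near the wPLI noise floor", {
  # pure independent noise: every pairwise wPLI below 0.1 for a 60 s record
  cfg <- simulationConfig(nSubjects = 1, duration = 60, seed = 13,
                          couplingSpec = list(), subjectGainSD = 0,
                          bandJitterSD = 0)
  rec <- simulateRecording(cfg, 1, "pre")
  sub <- EEGRecording(signals(rec)[seq(1, 56, by = 7), ],
                      samplingRate(rec))
  w <- weights(connectivityMatrix(sub, "alpha"))
  expect_lt(max(w), 0.1)
})

test_that("the injected alpha power elevation is recovered subject-wise", {
  # study-condition band shifts, short records: whole-brain mean alpha PSD
  # rises post in >= 45/48 subjects
  cfg <- simulationConfig(nSubjects = 48, duration = 5, seed = 17,
                          couplingSpec = list())
  coh <- simulateCohort(cfg)
  tab <- cohortBandTable(coh)
  a <- tab[tab$band == "alpha", ]
  pre <- a$value[a$condition == "pre"][order(a$subject[a$condition == "pre"])]
  post <- a$value[a$condition == "post"][order(a$subject[a$condition == "post"])]
  expect_gte(sum(post > pre), 45L)
})
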