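test_that("the normality gate accepts normal and rejects skewed samples", {
  set.seed(1)
  okNormal <- mean(replicate(50, normalityGate(rnorm(48))$normal))
  expect_gte(okNormal, 0.9)
  rejSkew <- mean(replicate(50, !normalityGate(rexp(48))$normal))
  expect_gte(rejSkew, 0.9)
  # Lilliefors variant behaves the same way
  expect_gte(mean(replicate(50, normalityGate(rnorm(48), "ks")$normal)), 0.9)
  expect_gte(mean(replicate(50, !normalityGate(rexp(48), "ks")$normal)), 0.9)
})

test_that("samples of n <= 3 are not evaluated, as in the omission rule", {
  g <- normalityGate(c(1, 2))
  expect_false(g$evaluated)
  expect_true(is.na(g$normal))
  expect_true(is.na(g$p))
})

test_that("paired test branches are a pure function of the gate", {
  set.seed(2)
  pre <- rnorm(30)
  post <- pre + 1 + rnorm(30, 0, 0.01)
  gateN <- list(p = 0.5, normal = TRUE, evaluated = TRUE, method = "shapiro")
  gateNN <- list(p = 0.01, normal = FALSE, evaluated = TRUE,
                 method = "shapiro")
  tN <- pairedTest(pre, post, gate = gateN)
  tNN <- pairedTest(pre, post, gate = gateNN)
  expect_identical(tN$test, "paired_t")
  expect_identical(tNN$test, "wilcoxon")
  expect_lt(tN$p, 0.001)
  expect_lt(tNN$p, 0.001)
  expect_gt(tN$d, 0)
  # ungated: gate computed internally, never a silent fallback
  tAuto <- pairedTest(pre, post)
  expect_true(tAuto$test %in% c("paired_t", "wilcoxon"))
  expect_error(pairedTest(pre, pre), "degenerate")
  expect_error(pairedTest(pre, post[-1]), "paired")
})

test_that("Cohen's d is the mean difference over the difference SD", {
  pre <- c(0, 0, 0)
  post <- c(0, 1, 2)   # differences: mean 1, sd 1
  gate <- list(p = 0.5, normal = TRUE, evaluated = TRUE, method = "shapiro")
  tt <- pairedTest(pre, post, gate = gate)
  expect_equal(tt$d, 1)
  expect_equal(tt$r, dToR(1))
})

test_that("under the null, paired-test p-values are close to uniform", {
  set.seed(3)
  ps <- replicate(200, {
    pre <- rnorm(30)
    post <- pre + rnorm(30)   # exchangeable conditions: no true change
    pairedTest(pre, post)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.001)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
})

test_that("the d <-> r conversion matches its closed forms and round-trips", {
  expect_equal(dToR(0), 0)
  expect_equal(dToR(2), 1 / sqrt(2))
  expect_equal(round(dToR(4.23), 2), 0.90)
  expect_equal(round(dToR(0.81), 2), 0.38)
  expect_equal(round(dToR(1.10), 2), 0.48)
  d <- seq(-10, 10, by = 0.25)
  expect_equal(rToD(dToR(d)), d, tolerance = 1e-12)
  expect_true(all(abs(dToR(d)) < 1))
  expect_true(all(diff(dToR(d)) > 0))          # monotone
  expect_equal(dToR(-d), -dToR(d))             # odd
})

test_that("Bonferroni thresholds reproduce the study families", {
  expect_equal(round(bonferroni(0.05, 3), 4), 0.0167)
  expect_equal(bonferroni(0.05, 5), 0.01)
  expect_equal(bonferroni(0.05, 10), 0.005)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0), "m must be")
})

test_that("the Wilcoxon effect size is Z/sqrt(N), with the literal Z/N flag", {
  set.seed(4)
  pre <- rnorm(25)
  post <- pre + rexp(25)   # strongly positive, non-normal differences
  gate <- list(p = 0.01, normal = FALSE, evaluated = TRUE, method = "shapiro")
  tt <- pairedTest(pre, post, gate = gate)
  ttLit <- pairedTest(pre, post, gate = gate, literalR = TRUE)
  expect_identical(tt$test, "wilcoxon")
  expect_equal(tt$r, tt$statistic / sqrt(25))
  expect_equal(ttLit$r, ttLit$statistic / 25)
  expect_gt(tt$r, 0)
  expect_true(abs(tt$r) <= 1)
})

test_that("Spearman correlation hits the rank extremes and guards input", {
  x <- c(1, 3, 7, 9, 20)
  expect_equal(spearmanCorrelation(x, x^3)$rho, 1)
  expect_equal(spearmanCorrelation(x, -x)$rho, -1)
  expect_error(spearmanCorrelation(x, rep(1, 5)), "constant")
  expect_error(spearmanCorrelation(x, c(1, 2)), "equal length")
  set.seed(5)
  nullRho <- replicate(100, spearmanCorrelation(rnorm(48), rnorm(48))$rho)
  expect_gte(mean(abs(nullRho) <= 0.4), 0.95)
})
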