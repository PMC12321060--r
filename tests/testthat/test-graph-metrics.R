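test_that("proportional thresholding keeps exactly the strongest edges", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  W <- W + t(W)
  net <- proportionalThreshold(W, 0.5)
  kept <- weights(net)[upper.tri(W)]
  expect_identical(sum(kept > 0), 3L)
  expect_setequal(kept[kept > 0], c(0.4, 0.5, 0.6))
  expect_gte(min(kept[kept > 0]), max(W[upper.tri(W)][kept == 0]))
  # p = 1 is the identity
  expect_equal(weights(proportionalThreshold(W, 1)), W)
  expect_error(proportionalThreshold(W, 0), "proportion")
  expect_error(proportionalThreshold(W, 1.2), "proportion")
})

test_that("tie-breaking on equal weights is deterministic", {
  W <- matrix(1, 6, 6); diag(W) <- 0
  a <- weights(proportionalThreshold(W, 0.5))
  b <- weights(proportionalThreshold(W, 0.5))
  expect_identical(a, b)
  expect_equal(sum(a[upper.tri(a)] > 0), round(0.5 * 15))
})

test_that("complete-graph and path-graph identities hold", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  gm <- globalMetrics(K3, nNull = 0)
  expect_equal(unname(gm[c("Eg", "Cp", "Lp")]), c(1, 1, 1))
  # unit-weight path A-B-C: pairs (A,B)=1, (B,C)=1, (A,C)=2
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- 1; P3[2, 3] <- P3[3, 2] <- 1
  gm <- globalMetrics(P3, nNull = 0)
  expect_equal(unname(gm["Lp"]), 4 / 3)
  expect_equal(unname(gm["Eg"]), 5 / 6)
  expect_equal(unname(gm["Cp"]), 0)
  expect_equal(unname(gm["Eloc"]), 0)
  expect_error(globalMetrics(matrix(0, 3, 3), nNull = 0), "no edges")
})

test_that("nodal metrics match hand-computed values", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  nm <- nodalMetrics(K4)
  expect_equal(unname(nm$NE), rep(1, 4))
  expect_equal(unname(nm$DC), rep(3, 4))
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- 1; P3[2, 3] <- P3[3, 2] <- 1
  nm <- nodalMetrics(P3)
  expect_equal(unname(nm$NE), c(3 / 4, 1, 3 / 4))
  expect_equal(unname(nm$DC), c(1, 2, 1))
  # isolated node contributes NE = DC = 0
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  nm <- nodalMetrics(W)
  expect_equal(unname(nm$NE[4]), 0)
  expect_equal(unname(nm$DC[4]), 0)
})

test_that("weighted distances use 1/weight edge lengths", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.5
  d <- netDistances(W)
  expect_equal(d[1, 2], 2)
  gm <- globalMetrics(W, nNull = 0)
  expect_equal(unname(gm["Eg"]), 0.5)
  expect_equal(unname(gm["Lp"]), 2)
})

test_that("shortest paths agree with a Floyd-Warshall oracle (fuzz)", {
  for (seed in 1:100) {
    n <- 4 + (seed %% 9)
    W <- randomWeightMatrix(n, p = 0.3 + 0.5 * (seed %% 5) / 4, seed = seed)
    if (all(W == 0)) next
    expect_equal(netDistances(W), fwDistances(W), tolerance = 1e-12)
  }
})

test_that("node relabeling permutes nodal and preserves global metrics", {
  W <- randomWeightMatrix(10, 0.4, seed = 77)
  perm <- sample(10)
  Wp <- W[perm, perm]
  gm <- globalMetrics(W, nNull = 0)
  gmp <- globalMetrics(Wp, nNull = 0)
  expect_equal(gm[c("Eg", "Eloc", "Cp", "Lp")],
               gmp[c("Eg", "Eloc", "Cp", "Lp")])
  nm <- nodalMetrics(W); nmp <- nodalMetrics(Wp)
  expect_equal(unname(nmp$NE), unname(nm$NE[perm]))
  expect_equal(unname(nmp$DC), unname(nm$DC[perm]))
})

test_that("Eg is nondecreasing and Lp nonincreasing along the sweep", {
  W <- randomWeightMatrix(20, 0.9, seed = 5)   # dense, stays connected
  sw <- thresholdSweep(W, proportions = seq(0.2, 0.6, by = 0.1))
  expect_true(all(diff(sw$Eg) >= -1e-12))
  expect_true(all(diff(sw$Lp) <= 1e-12))
  # single-proportion sweep equals globalMetrics
  one <- thresholdSweep(W, proportions = 0.3)
  gm <- globalMetrics(proportionalThreshold(W, 0.3), nNull = 0)
  expect_equal(unlist(one[1, c("Eg", "Eloc", "Cp", "Lp")]),
               gm[c("Eg", "Eloc", "Cp", "Lp")], ignore_attr = TRUE)
  expect_error(thresholdSweep(W, proportions = numeric()), "non-empty")
  expect_error(thresholdSweep(W, proportions = c(0.5, 0.3)), "ascending")
})

test_that("a mildly rewired ring lattice is small-world (Sigma > 1)", {
  W <- ringLattice(24, 3, pr = 0.1, seed = 3)
  gm <- globalMetrics(W, nNull = 50, nullSeed = 9)
  expect_gt(unname(gm["Sigma"]), 1)
})

test_that("Sigma nulls are seeded and do not disturb the caller's RNG", {
  W <- randomWeightMatrix(15, 0.4, seed = 21)
  g1 <- globalMetrics(W, nNull = 20, nullSeed = 4)
  set.seed(999); before <- runif(1)
  set.seed(999)
  g2 <- globalMetrics(W, nNull = 20, nullSeed = 4)
  after <- runif(1)
  expect_identical(g1, g2)
  expect_identical(before, after)
})

test_that("region means aggregate nodal metrics over montage channels", {
  m <- defaultMontage()
  set.seed(8)
  W <- randomWeightMatrix(56, 0.3, seed = 8)
  dimnames(W) <- list(channels(m), channels(m))
  nm <- nodalMetrics(W, montage = m)
  expect_identical(nrow(nm$regionMeans), 10L)
  occ <- regionMask(m, "occipital")
  expect_equal(nm$regionMeans$NE[nm$regionMeans$region == "occipital"],
               mean(nm$NE[occ]))
  # montage mismatch
  expect_error(nodalMetrics(W[1:10, 1:10], montage = m), "montage")
})
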