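# Independent brute-force oracles and small fixture builders.

# Floyd-Warshall all-pairs shortest paths on a weight matrix, edge length
# 1/weight. Independent of the igraph-based implementation under test.
fwDistances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Random symmetric weight matrix: n nodes, edge density p, U(0.1, 1) weights.
randomWeightMatrix <- function(n, p, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  on <- stats::runif(sum(ut)) < p
  w <- stats::runif(sum(ut), 0.1, 1)
  W[ut] <- ifelse(on, w, 0)
  W + t(W)
}

# Unweighted ring lattice: n nodes, each joined to k nearest neighbours per
# side, then a fraction pr of edges rewired to random endpoints.
ringLattice <- function(n, k, pr = 0, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n))
    for (s in seq_len(k)) {
      j <- ((i - 1 + s) %% n) + 1
      W[i, j] <- W[j, i] <- 1
    }
  if (pr > 0) {
    idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    for (e in seq_len(nrow(idx))) {
      if (stats::runif(1) < pr) {
        i <- idx[e, 1]
        cand <- which(W[i, ] == 0 & seq_len(n) != i)
        if (length(cand)) {
          j <- if (length(cand) == 1) cand else sample(cand, 1)
          W[idx[e, 1], idx[e, 2]] <- W[idx[e, 2], idx[e, 1]] <- 0
          W[i, j] <- W[j, i] <- 1
        }
      }
    }
  }
  W
}

# Minimal coupled-pair simulation config: two montage channels sharing an
# alpha carrier at a given lag and strength, no background noise, no jitter.
coupledPairConfig <- function(lag, strength = 1, duration = 20, seed = 42,
                              channels = c("C3", "C4")) {
  simulationConfig(
    nSubjects = 1, duration = duration, seed = seed,
    bandPower = list(alpha = c(pre = 1, post = 1)),
    couplingSpec = list(list(channels = channels, band = "alpha",
                             lagStep = lag, strength = c(pre = strength,
                                                         post = strength),
                             masterMix = c(pre = 0, post = 0),
                             masterLag = 0)),
    noiseVariance = 0, subjectGainSD = 0, bandJitterSD = 0,
    couplingJitterSD = 0, amplitudeJitter = 0)
}
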