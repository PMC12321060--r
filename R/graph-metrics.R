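## Proportional thresholding and weighted graph-theory metrics.
##
## Conventions (weighted throughout, never binarized):
##   * edge length for shortest paths = 1 / weight;
##   * global efficiency Eg = mean over ordered node pairs of 1/d(i,j),
##     disconnected pairs contributing 0;
##   * characteristic path length Lp = mean d(i,j) over connected pairs;
##   * clustering Cp = Onnela geometric-mean triangle intensity, weights
##     normalized by the network maximum, averaged over all nodes (nodes of
##     degree < 2 contribute 0);
##   * local efficiency Eloc = mean over nodes of the global efficiency of
##     the subgraph induced by each node's neighbors (Latora-Marchiori);
##   * small-world Sigma = (Cp/Cp_rand) / (Lp/Lp_rand), null means over
##     degree-preserving Maslov-Sneppen rewired surrogates that carry the
##     original weights on the swapped edges;
##   * nodal efficiency NE(i) = mean over j != i of 1/d(i,j);
##   * degree centrality DC(i) = node strength, the sum of retained incident
##     weights.

.asWeightMatrix <- function(x) {
  if (is(x, "ConnectivityMatrix") || is(x, "ThresholdedNetwork"))
    return(x@weights)
  if (is.matrix(x)) return(x)
  stop("expected a ConnectivityMatrix, ThresholdedNetwork or matrix")
}

#' Proportional thresholding
#'
#' Keeps exactly \code{round(proportion * n(n-1)/2)} of the strongest
#' off-diagonal edges (weights preserved, not binarized); ties are broken by
#' lexicographic (row, column) order so the selection is reproducible.
#'
#' @param x a \linkS4class{ConnectivityMatrix} or symmetric weight matrix.
#' @param proportion fraction of possible edges to retain, in (0, 1].
#' @return a \linkS4class{ThresholdedNetwork}.
#' @examples
#' w <- matrix(0, 4, 4); w[upper.tri(w)] <- (1:6)/10; w <- w + t(w)
#' proportionalThreshold(w, 0.5)   # keeps the 3 largest edges
#' @export
proportionalThreshold <- function(x, proportion) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must be in (0, 1]")
  W <- .asWeightMatrix(x)
  n <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  k <- round(proportion * nrow(idx))
  ord <- order(-W[idx], idx[, 1], idx[, 2])
  keep <- idx[ord[seq_len(k)], , drop = FALSE]
  Wt <- matrix(0, n, n, dimnames = dimnames(W))
  Wt[keep] <- W[keep]
  Wt <- Wt + t(Wt)
  new("ThresholdedNetwork", weights = Wt, proportion = proportion)
}

## Shortest-path distance matrix with edge length 1/weight.
.netDistances <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(W), ncol(W), dimnames = dimnames(W))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Shortest-path distances of a thresholded network
#'
#' @param net a \linkS4class{ThresholdedNetwork} (or weight matrix).
#' @return symmetric matrix of shortest-path lengths using edge length
#'   1/weight; \code{Inf} for disconnected pairs.
#' @export
netDistances <- function(net) .netDistances(.asWeightMatrix(net))

.globalEfficiency <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

.charPathLength <- function(d) {
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (!length(off)) return(NA_real_)
  mean(off)
}

.onnelaClustering <- function(W) {
  mx <- max(W)
  if (mx == 0) return(0)
  Wh <- (W / mx)^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  cp <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(cp)
}

.localEfficiency <- function(W) {
  n <- nrow(W)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    .globalEfficiency(.netDistances(W[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(vals)
}

## Maslov-Sneppen degree-preserving rewiring (double-edge swaps, via
## igraph's C implementation); the multiset of edge weights is preserved by
## reassigning the original weights at random onto the rewired edge list.
.rewireWeights <- function(W, nSwapPerEdge = 10) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2) return(W)
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  g <- igraph::rewire(g, igraph::keeping_degseq(niter = nSwapPerEdge * m))
  ends <- igraph::as_edgelist(g, names = FALSE)
  Wn <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  Wn[ends] <- sample(W[idx])
  Wn + t(Wn)
}

#' Global graph-theory metrics
#'
#' Computes the five global topology metrics of a thresholded weighted
#' network: global efficiency (Eg), local efficiency (Eloc), clustering
#' coefficient (Cp), characteristic path length (Lp) and the small-world
#' index Sigma = (Cp/Cp_rand)/(Lp/Lp_rand), where the null means are taken
#' over \code{nNull} degree-preserving rewired surrogates.
#'
#' @param net a \linkS4class{ThresholdedNetwork} (or weight matrix).
#' @param nNull number of null surrogates for Sigma (default 100; 0 skips
#'   Sigma, returning NA).
#' @param nullSeed integer seed for the surrogate generator.
#' @return named numeric: Eg, Eloc, Cp, Lp, Sigma.
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0   # unweighted triangle
#' globalMetrics(w, nNull = 0)          # Eg = Cp = Lp = 1
#' @export
globalMetrics <- function(net, nNull = 100, nullSeed = 1) {
  W <- .asWeightMatrix(net)
  if (all(W == 0)) stop("network has no edges")
  d <- .netDistances(W)
  Eg <- .globalEfficiency(d)
  Lp <- .charPathLength(d)
  Cp <- .onnelaClustering(W)
  Eloc <- .localEfficiency(W)
  Sigma <- NA_real_
  if (nNull > 0) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(nullSeed)
    cpR <- numeric(nNull); lpR <- numeric(nNull)
    for (r in seq_len(nNull)) {
      Wr <- .rewireWeights(W)
      cpR[r] <- .onnelaClustering(Wr)
      lpR[r] <- .charPathLength(.netDistances(Wr))
    }
    cpBar <- mean(cpR); lpBar <- mean(lpR, na.rm = TRUE)
    if (!is.finite(cpBar) || cpBar <= 0 || !is.finite(lpBar) || lpBar <= 0)
      stop("null generation failed (degenerate surrogate metrics)")
    Sigma <- (Cp / cpBar) / (Lp / lpBar)
  }
  c(Eg = Eg, Eloc = Eloc, Cp = Cp, Lp = Lp, Sigma = Sigma)
}

## Save/restore the global RNG state so seeded null generation does not
## disturb a caller's random stream.
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Nodal graph-theory metrics
#'
#' Nodal efficiency NE(i) = mean over j != i of 1/d(i,j) (0 for unreachable
#' pairs) and degree centrality DC(i) = node strength (sum of retained
#' incident weights), plus per-region means when a montage is supplied.
#'
#' @param net a \linkS4class{ThresholdedNetwork} (or weight matrix).
#' @param montage optional \linkS4class{EEGMontage}; its channel order must
#'   match the network's nodes.
#' @return list with \code{NE}, \code{DC} (named numeric per node) and, when
#'   a montage is given, \code{regionMeans}: data.frame(region, NE, DC).
#' @export
nodalMetrics <- function(net, montage = NULL) {
  W <- .asWeightMatrix(net)
  d <- .netDistances(W)
  n <- nrow(W)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  NE <- rowSums(inv) / (n - 1)
  DC <- rowSums(W)
  names(NE) <- names(DC) <- rownames(W)
  out <- list(NE = NE, DC = DC)
  if (!is.null(montage)) {
    if (n != length(montage@channels) ||
        (!is.null(rownames(W)) &&
         !identical(rownames(W), montage@channels)))
      stop("network nodes do not match the montage channels")
    rm <- lapply(names(montage@regions), function(rg) {
      i <- regionMask(montage, rg)
      data.frame(region = rg, NE = mean(NE[i]), DC = mean(DC[i]))
    })
    out$regionMeans <- do.call(rbind, rm)
  }
  out
}

#' Global metrics across a proportional-threshold sweep
#'
#' @param x a \linkS4class{ConnectivityMatrix} or weight matrix.
#' @param proportions ascending vector of retention proportions (default
#'   0.10 to 0.50 in steps of 0.05).
#' @param nNull null surrogates per proportion for Sigma (default 0 = skip).
#' @param nullSeed seed for the surrogates.
#' @return data.frame with columns proportion, Eg, Eloc, Cp, Lp, Sigma.
#' @export
thresholdSweep <- function(x, proportions = seq(0.10, 0.50, by = 0.05),
                           nNull = 0, nullSeed = 1) {
  if (!length(proportions)) stop("proportions must be non-empty")
  if (is.unsorted(proportions)) stop("proportions must be sorted ascending")
  rows <- lapply(proportions, function(p) {
    gm <- globalMetrics(proportionalThreshold(x, p), nNull = nNull,
                        nullSeed = nullSeed)
    data.frame(proportion = p, t(gm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
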