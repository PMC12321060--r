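## Paired statistics layer: normality gating, paired t / Wilcoxon signed-rank
## with effect sizes, Bonferroni families, Spearman correlation.

#' Normality gate for paired differences
#'
#' Shapiro-Wilk or Lilliefors (Kolmogorov-Smirnov with estimated parameters)
#' test of the paired differences. Samples of n <= 3 are not evaluated
#' (gate status "not evaluated"), mirroring the study's omission rule for
#' small groups; downstream they are routed to the nonparametric branch.
#'
#' @param x numeric vector (typically post - pre differences).
#' @param method "shapiro" (default) or "ks" (Lilliefors).
#' @param alpha gate level (default 0.05).
#' @return list: \code{p}, \code{normal} (TRUE/FALSE, or NA when not
#'   evaluated), \code{evaluated}, \code{method}.
#' @export
normalityGate <- function(x, method = c("shapiro", "ks"), alpha = 0.05) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  n <- length(x)
  minN <- if (method == "shapiro") 4L else 5L
  if (n <= 3L || n < minN)
    return(list(p = NA_real_, normal = NA, evaluated = FALSE,
                method = method))
  if (stats::sd(x) == 0)
    return(list(p = 0, normal = FALSE, evaluated = TRUE, method = method))
  p <- if (method == "shapiro") stats::shapiro.test(x)$p.value
       else nortest::lillie.test(x)$p.value
  list(p = p, normal = p > alpha, evaluated = TRUE, method = method)
}

#' Cohen's d to effect-size r
#'
#' r = d / sqrt(d^2 + 4); odd, monotone, |r| < 1.
#'
#' @param d Cohen's d (finite).
#' @return r.
#' @examples
#' dToR(4.23)   # 0.90 to two decimals
#' @export
dToR <- function(d) {
  stopifnot(all(is.finite(d)))
  d / sqrt(d^2 + 4)
}

#' Effect-size r to Cohen's d (inverse conversion)
#'
#' @param r effect size with |r| < 1.
#' @return d = 2 r / sqrt(1 - r^2).
#' @export
rToD <- function(r) {
  stopifnot(all(abs(r) < 1))
  2 * r / sqrt(1 - r^2)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests in the family, >= 1.
#' @return alpha' = alpha / m.
#' @examples
#' bonferroni(0.05, 3)   # 0.0167 to four decimals
#' @export
bonferroni <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

## Wilcoxon signed-rank: V statistic, normal-approximation Z with continuity
## and tie corrections, and a p-value (exact for small untied samples).
.wilcoxonSignedRank <- function(diffs) {
  nz <- diffs[diffs != 0]
  np <- length(nz)
  if (np == 0) stop("degenerate sample: all paired differences are zero")
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  mu <- np * (np + 1) / 4
  tie <- table(r)
  sig2 <- np * (np + 1) * (2 * np + 1) / 24 - sum(tie^3 - tie) / 48
  Z <- if (V == mu) 0 else (V - mu - 0.5 * sign(V - mu)) / sqrt(sig2)
  exactOK <- np < 20 && !any(duplicated(abs(nz))) && length(nz) == length(diffs)
  p <- if (exactOK)
    suppressWarnings(stats::wilcox.test(nz, exact = TRUE)$p.value)
  else 2 * stats::pnorm(-abs(Z))
  list(V = V, Z = Z, p = min(p, 1))
}

#' Paired pre/post test with normality-gated branching
#'
#' Parametric branch (paired t-test) when the gate declares the differences
#' normal: Cohen's d = mean(diff)/sd(diff), r via \code{\link{dToR}}.
#' Nonparametric branch (Wilcoxon signed-rank) when the gate fails or was
#' not evaluated: effect size r = Z/sqrt(N) with N the number of pairs
#' (the literal printed form Z/N is available for audit via
#' \code{literalR = TRUE}). The branch choice is a pure function of the gate;
#' there is no silent fallback.
#'
#' @param pre,post numeric vectors of equal length (per-subject values).
#' @param gate result of \code{\link{normalityGate}} on \code{post - pre};
#'   computed with \code{gateMethod} if omitted.
#' @param gateMethod method for the gate when it is computed here.
#' @param alphaPrime adjusted significance threshold recorded in the result.
#' @param literalR use the literal r = Z/N form (default FALSE).
#' @param label optional label for the measured quantity.
#' @return list: test ("paired_t" or "wilcoxon"), p, statistic, d (NA on the
#'   nonparametric branch), r, n, normality_p, significant (p < alphaPrime),
#'   alphaPrime, label.
#' @export
pairedTest <- function(pre, post, gate = NULL,
                       gateMethod = c("shapiro", "ks"), alphaPrime = 0.05,
                       literalR = FALSE, label = NA_character_) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  if (length(pre) < 2) stop("need at least 2 pairs")
  if (anyNA(pre) || anyNA(post)) stop("missing pairs are not allowed")
  diffs <- post - pre
  if (all(diffs == 0)) stop("degenerate sample: all paired differences are zero")
  if (is.null(gate)) gate <- normalityGate(diffs, match.arg(gateMethod))
  n <- length(diffs)
  if (isTRUE(gate$normal)) {
    tt <- stats::t.test(post, pre, paired = TRUE)
    d <- mean(diffs) / stats::sd(diffs)
    res <- list(test = "paired_t", p = tt$p.value,
                statistic = unname(tt$statistic), d = d, r = dToR(d))
  } else {
    w <- .wilcoxonSignedRank(diffs)
    r <- if (literalR) w$Z / n else w$Z / sqrt(n)
    res <- list(test = "wilcoxon", p = w$p, statistic = w$Z, d = NA_real_,
                r = r)
  }
  c(res, list(n = n, normality_p = gate$p, significant = res$p < alphaPrime,
              alphaPrime = alphaPrime, label = label))
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors of equal length >= 3; constant input is an
#'   error (the rank correlation is undefined).
#' @return list: rho, p.
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
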