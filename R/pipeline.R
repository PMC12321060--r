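## Study orchestration: band table -> band statistics -> sensitive-band
## selection -> wPLI networks -> graph metrics -> statistics families ->
## fatigue correlation.

#' Pipeline configuration
#'
#' @param estimator connectivity estimator, "paper_formula" (default) or
#'   "standard_wpli".
#' @param segmentLength Welch segment length in samples (default NULL =
#'   2 seconds at the cohort's sampling rate).
#' @param overlap Welch segment overlap (default 0.5).
#' @param statProportion the retention proportion at which the statistics
#'   families are tested (default 0.25).
#' @param proportions proportions for the threshold-sweep curves.
#' @param nNull null surrogates for Sigma at the statistics proportion.
#' @param sweepNull null surrogates for Sigma along the sweep (default 20).
#' @param alpha family-wise significance level (default 0.05).
#' @param mBands,mGlobal,mLocal Bonferroni family sizes: 3 bands, 5 global
#'   metrics, 10 regions (alpha' = 0.0167, 0.01, 0.005 at alpha = 0.05).
#' @param literalR use the literal Wilcoxon effect size r = Z/N instead of
#'   Z/sqrt(N) (audit flag; default FALSE).
#' @param includeSweep compute group-mean threshold-sweep curves.
#' @param keepMatrices retain per-recording connectivity matrices in the
#'   report (default FALSE).
#' @param seed root seed for all stochastic steps (Sigma null surrogates).
#' @return a list of class "studyConfig".
#' @export
studyConfig <- function(estimator = c("paper_formula", "standard_wpli"),
                        segmentLength = NULL, overlap = 0.5,
                        statProportion = 0.25,
                        proportions = seq(0.10, 0.50, by = 0.05),
                        nNull = 100, sweepNull = 20, alpha = 0.05,
                        mBands = 3, mGlobal = 5, mLocal = 10,
                        literalR = FALSE, includeSweep = TRUE,
                        keepMatrices = FALSE, seed = 1) {
  if (any(c(mBands, mGlobal, mLocal) < 1))
    stop("Bonferroni family sizes must be positive")
  structure(list(estimator = match.arg(estimator),
                 segmentLength = segmentLength, overlap = overlap,
                 statProportion = statProportion, proportions = proportions,
                 nNull = nNull, sweepNull = sweepNull, alpha = alpha,
                 mBands = mBands, mGlobal = mGlobal, mLocal = mLocal,
                 literalR = literalR, includeSweep = includeSweep,
                 keepMatrices = keepMatrices, seed = seed),
            class = "studyConfig")
}

#' Select the fatigue-sensitive band
#'
#' Returns the band whose paired-comparison effect size has the largest
#' magnitude |r|; exact ties are broken by the fixed order theta < alpha <
#' beta with a warning.
#'
#' @param bandTests data.frame with columns \code{band} and \code{r} (one row
#'   per tested band).
#' @return character scalar, the selected band name.
#' @examples
#' selectSensitiveBand(data.frame(band = c("theta", "alpha", "beta"),
#'                                r = c(0.38, 0.90, 0.27)))
#' @export
selectSensitiveBand <- function(bandTests) {
  if (is.null(bandTests) || nrow(bandTests) < 1)
    stop("no band results to select from")
  ord <- c("theta", "alpha", "beta")
  bandTests <- bandTests[order(match(bandTests$band, ord)), ]
  absr <- abs(bandTests$r)
  best <- which(absr == max(absr))
  if (length(best) > 1)
    warning("effect-size tie between bands ",
            paste(bandTests$band[best], collapse = ", "),
            "; keeping the first in theta < alpha < beta order",
            call. = FALSE)
  bandTests$band[best[1]]
}

.cohortParts <- function(cohort) {
  if (is(cohort, "SyntheticCohort"))
    return(list(recordings = cohort@recordings, vasf = cohort@vasf))
  if (is.list(cohort) && !is.null(cohort$recordings))
    return(list(recordings = cohort$recordings, vasf = cohort$vasf))
  stop("cohort must be a SyntheticCohort or a list with $recordings")
}

## Paired pre/post vectors for one measured quantity from a tidy table.
.pairedFromTable <- function(tab, valueCol = "value") {
  subj <- sort(unique(tab$subject))
  pre <- tab[[valueCol]][match(paste0(subj, "_pre"),
                               paste0(tab$subject, "_", tab$condition))]
  post <- tab[[valueCol]][match(paste0(subj, "_post"),
                                paste0(tab$subject, "_", tab$condition))]
  if (anyNA(pre) || anyNA(post)) stop("missing pre/post pairs")
  list(subject = subj, pre = pre, post = post)
}

.testRow <- function(tt, label, extra = list()) {
  data.frame(c(list(label = label, test = tt$test, p = tt$p,
                    statistic = tt$statistic, d = tt$d, r = tt$r,
                    normality_p = ifelse(is.na(tt$normality_p), NA,
                                         tt$normality_p),
                    alphaPrime = tt$alphaPrime,
                    significant = tt$significant), extra))
}

#' Run the full pre/post study pipeline
#'
#' Orchestrates the whole analysis on a paired cohort: (1) whole-brain band
#' powers and paired band statistics (Lilliefors-gated, Bonferroni family of
#' \code{mBands}); (2) selection of the most fatigue-sensitive band by |r|;
#' (3) wPLI connectivity in the selected band per recording, proportional
#' thresholding at \code{statProportion}; (4) global metric family (5 tests,
#' Shapiro-gated) and local NE/DC region families (10 regions each; regions
#' with 3 or fewer channels skip the normality gate and use Wilcoxon);
#' (5) Spearman correlation of metric changes against the change in the
#' VAS-F fatigue score; (6) optional group-mean threshold-sweep curves.
#' Deterministic given the config seed.
#'
#' @param cohort a \linkS4class{SyntheticCohort} or a list with
#'   \code{$recordings} (list of \linkS4class{EEGRecording}) and optional
#'   \code{$vasf} score table.
#' @param config a \code{\link{studyConfig}}.
#' @param montage the \linkS4class{EEGMontage} (default
#'   \code{defaultMontage()}).
#' @param outDir optional directory; when given the report tables are written
#'   there as tab-separated text plus a JSON run log.
#' @return list of class "studyReport": \code{bandTable}, \code{bandTests},
#'   \code{selectedBand}, \code{metricTable}, \code{globalTests},
#'   \code{localTests}, \code{vasfTests}, \code{correlation}, \code{sweep},
#'   \code{runLog} (and \code{matrices} when \code{keepMatrices}).
#' @export
runStudy <- function(cohort, config = studyConfig(),
                     montage = defaultMontage(), outDir = NULL) {
  parts <- .cohortParts(cohort)
  recs <- parts$recordings
  vasf <- parts$vasf

  ## ---- VAS-F manipulation check -------------------------------------
  vasfTests <- NULL
  if (!is.null(vasf)) {
    vasfTests <- do.call(rbind, lapply(c("fatigue", "energy"), function(sc) {
      pp <- .pairedFromTable(vasf, sc)
      tt <- pairedTest(pp$pre, pp$post, gateMethod = "shapiro",
                       alphaPrime = config$alpha, literalR = config$literalR,
                       label = sc)
      .testRow(tt, sc)
    }))
  }

  ## ---- band powers and band statistics ------------------------------
  bandTable <- cohortBandTable(recs, segmentLength = config$segmentLength,
                               overlap = config$overlap)
  aBands <- bonferroni(config$alpha, config$mBands)
  bandTests <- do.call(rbind, lapply(names(eegBands()), function(b) {
    tab <- bandTable[bandTable$band == b, ]
    pp <- .pairedFromTable(tab)
    tt <- pairedTest(pp$pre, pp$post, gateMethod = "ks",
                     alphaPrime = aBands, literalR = config$literalR,
                     label = b)
    .testRow(tt, b, list(band = b, meanChange = mean(pp$post - pp$pre)))
  }))
  selectedBand <- selectSensitiveBand(bandTests)

  ## ---- connectivity and graph metrics per recording -----------------
  subjects <- sort(unique(vapply(recs, function(r) r@subject, character(1))))
  metricRows <- list()
  matrices <- if (config$keepMatrices) list() else NULL
  meanW <- list(pre = 0, post = 0)
  nW <- list(pre = 0L, post = 0L)
  globalNames <- c("Eg", "Eloc", "Cp", "Lp", "Sigma")
  for (si in seq_along(subjects)) {
    for (cond in c("pre", "post")) {
      rec <- NULL
      for (r in recs)
        if (r@subject == subjects[si] && r@condition == cond) { rec <- r; break }
      if (is.null(rec))
        stop("stage connectivity, subject ", subjects[si],
             ": missing ", cond, " recording")
      cm <- connectivityMatrix(rec, band = selectedBand,
                               estimator = config$estimator,
                               montage = montage)
      net <- proportionalThreshold(cm, config$statProportion)
      icond <- if (cond == "pre") 1L else 2L
      gm <- globalMetrics(net, nNull = config$nNull,
                          nullSeed = .deriveSeed(config$seed, si, icond, 7L))
      nm <- nodalMetrics(net, montage = montage)
      metricRows[[length(metricRows) + 1L]] <- rbind(
        data.frame(subject = subjects[si], condition = cond,
                   proportion = config$statProportion, metric = globalNames,
                   region = NA_character_, value = unname(gm[globalNames])),
        data.frame(subject = subjects[si], condition = cond,
                   proportion = config$statProportion,
                   metric = rep(c("NE", "DC"),
                                each = nrow(nm$regionMeans)),
                   region = rep(nm$regionMeans$region, 2),
                   value = c(nm$regionMeans$NE, nm$regionMeans$DC)))
      meanW[[cond]] <- meanW[[cond]] + weights(cm)
      nW[[cond]] <- nW[[cond]] + 1L
      if (config$keepMatrices)
        matrices[[paste0(subjects[si], "_", cond)]] <- cm
    }
  }
  metricTable <- do.call(rbind, metricRows)
  rownames(metricTable) <- NULL

  ## ---- global metric family ------------------------------------------
  aGlobal <- bonferroni(config$alpha, config$mGlobal)
  globalTests <- do.call(rbind, lapply(globalNames, function(mName) {
    tab <- metricTable[metricTable$metric == mName &
                       is.na(metricTable$region), ]
    if (anyNA(tab$value)) return(NULL)    # e.g. Sigma skipped when nNull = 0
    pp <- .pairedFromTable(tab)
    tt <- pairedTest(pp$pre, pp$post, gateMethod = "shapiro",
                     alphaPrime = aGlobal, literalR = config$literalR,
                     label = mName)
    .testRow(tt, mName, list(metric = mName,
                             meanChange = mean(pp$post - pp$pre)))
  }))

  ## ---- local metric families -----------------------------------------
  aLocal <- bonferroni(config$alpha, config$mLocal)
  regionSizes <- vapply(regions(montage), length, integer(1))
  localTests <- do.call(rbind, lapply(c("NE", "DC"), function(mName) {
    do.call(rbind, lapply(names(regions(montage)), function(rg) {
      tab <- metricTable[metricTable$metric == mName &
                         !is.na(metricTable$region) &
                         metricTable$region == rg, ]
      pp <- .pairedFromTable(tab)
      gate <- if (regionSizes[[rg]] <= 3)
        list(p = NA_real_, normal = NA, evaluated = FALSE, method = "shapiro")
      else normalityGate(pp$post - pp$pre, "shapiro")
      tt <- pairedTest(pp$pre, pp$post, gate = gate, alphaPrime = aLocal,
                       literalR = config$literalR, label = rg)
      .testRow(tt, rg, list(metric = mName, region = rg,
                            meanChange = mean(pp$post - pp$pre),
                            preMean = mean(pp$pre), preSD = stats::sd(pp$pre),
                            postMean = mean(pp$post),
                            postSD = stats::sd(pp$post)))
    }))
  }))

  ## ---- correlation with subjective fatigue ----------------------------
  correlation <- NULL
  if (!is.null(vasf)) {
    ppF <- .pairedFromTable(vasf, "fatigue")
    dFatigue <- ppF$post - ppF$pre
    corrTargets <- list(
      Eg = c("Eg", NA), Eloc = c("Eloc", NA), Lp = c("Lp", NA),
      Cp = c("Cp", NA),
      `NE frontal` = c("NE", "frontal"),
      `NE parietal` = c("NE", "parietal"),
      `NE central` = c("NE", "central"),
      `NE centro-parietal` = c("NE", "centro-parietal"))
    correlation <- do.call(rbind, lapply(names(corrTargets), function(lbl) {
      tg <- corrTargets[[lbl]]
      tab <- if (is.na(tg[2]))
        metricTable[metricTable$metric == tg[1] & is.na(metricTable$region), ]
      else metricTable[metricTable$metric == tg[1] &
                       !is.na(metricTable$region) &
                       metricTable$region == tg[2], ]
      pp <- .pairedFromTable(tab)
      sc <- spearmanCorrelation(pp$post - pp$pre,
                                dFatigue[match(pp$subject, ppF$subject)])
      data.frame(label = lbl, rho = sc$rho, p = sc$p)
    }))
  }

  ## ---- group-mean threshold sweep --------------------------------------
  sweep <- NULL
  if (config$includeSweep) {
    sweep <- do.call(rbind, lapply(c("pre", "post"), function(cond) {
      sw <- thresholdSweep(meanW[[cond]] / nW[[cond]],
                           proportions = config$proportions,
                           nNull = config$sweepNull,
                           nullSeed = .deriveSeed(config$seed, 0L,
                                                  if (cond == "pre") 1L else 2L,
                                                  9L))
      cbind(condition = cond, sw)
    }))
  }

  report <- structure(list(
    bandTable = bandTable, bandTests = bandTests,
    selectedBand = selectedBand, metricTable = metricTable,
    globalTests = globalTests, localTests = localTests,
    vasfTests = vasfTests, correlation = correlation, sweep = sweep,
    matrices = matrices,
    runLog = list(nSubjects = length(subjects),
                  estimator = config$estimator,
                  statProportion = config$statProportion,
                  nNull = config$nNull, alpha = config$alpha,
                  alphaPrime = list(bands = aBands, global = aGlobal,
                                    local = aLocal),
                  selectedBand = selectedBand, seed = config$seed)),
    class = "studyReport")
  if (!is.null(outDir)) writeStudyReport(report, outDir)
  report
}

#' @export
print.studyReport <- function(x, ...) {
  cat("Study report\n")
  cat("  selected band:", x$selectedBand, "\n")
  cat("  band tests (alpha' =", format(x$bandTests$alphaPrime[1], digits = 3),
      "):\n")
  print(x$bandTests[, c("band", "test", "p", "r", "significant")],
        row.names = FALSE, digits = 3)
  cat("  global metric tests (alpha' =",
      format(x$globalTests$alphaPrime[1], digits = 3), "):\n")
  print(x$globalTests[, c("metric", "test", "p", "meanChange",
                          "significant")], row.names = FALSE, digits = 3)
  sigLoc <- x$localTests[x$localTests$significant, c("metric", "region", "p")]
  cat("  significant local changes (alpha' =",
      format(x$localTests$alphaPrime[1], digits = 3), "):",
      if (nrow(sigLoc)) "\n" else "none\n")
  if (nrow(sigLoc)) print(sigLoc, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a study report to disk
#'
#' Tab-separated tables plus a JSON run log, mirroring the layout of the
#' report object.
#'
#' @param report a "studyReport" from \code{\link{runStudy}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$bandTable, "band_table")
  wt(report$bandTests, "band_tests")
  wt(report$metricTable, "metric_table")
  wt(report$globalTests, "global_tests")
  wt(report$localTests, "local_tests")
  wt(report$vasfTests, "vasf_tests")
  wt(report$correlation, "correlation")
  wt(report$sweep, "threshold_sweep")
  writeLines(jsonlite::toJSON(report$runLog, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "run_log.json"))
  invisible(dir)
}
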