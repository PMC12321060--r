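## Plain-text recording and cohort I/O: a delimited channels x samples matrix
## per recording plus a JSON sidecar with the metadata, and a cohort-level
## JSON manifest retaining the simulation truth parameters.

#' Write a recording as delimited text plus JSON sidecar
#'
#' Produces \code{<basePath>.tsv} (channels x samples, channel labels as the
#' first column) and \code{<basePath>.json} (fs, subject, condition,
#' channels).
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param basePath file path without extension.
#' @return invisibly, the two file paths.
#' @export
writeRecording <- function(recording, basePath) {
  tsv <- paste0(basePath, ".tsv")
  meta <- paste0(basePath, ".json")
  utils::write.table(signals(recording), tsv, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  writeLines(jsonlite::toJSON(list(fs = samplingRate(recording),
                                   subject = recording@subject,
                                   condition = recording@condition,
                                   channels = channels(recording)),
                              auto_unbox = TRUE, digits = NA),
             meta)
  invisible(c(tsv, meta))
}

#' Read a recording written by \code{\link{writeRecording}}
#'
#' @param basePath file path without extension.
#' @return an \linkS4class{EEGRecording}.
#' @export
readRecording <- function(basePath) {
  meta <- jsonlite::fromJSON(paste0(basePath, ".json"))
  m <- utils::read.table(paste0(basePath, ".tsv"), sep = "\t",
                         row.names = 1, header = FALSE)
  m <- as.matrix(m)
  colnames(m) <- NULL
  if (!identical(rownames(m), as.character(meta$channels)))
    stop("sidecar channel list does not match the matrix rows")
  EEGRecording(m, fs = meta$fs, subject = meta$subject,
               condition = meta$condition)
}

#' Write a synthetic cohort to a directory
#'
#' One recording (TSV + JSON sidecar) per subject-condition, a VAS-F score
#' table, and \code{manifest.json} listing subjects, conditions, file paths
#' and the truth parameters of the generating configuration.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(cohort@recordings)) {
    writeRecording(cohort@recordings[[nm]], file.path(dir, nm))
    paths[nm] <- paste0(nm, ".tsv")
  }
  utils::write.table(cohort@vasf, file.path(dir, "vasf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort@truth
  truth <- list(nSubjects = cfg@nSubjects, fs = cfg@fs,
                duration = cfg@duration, bandPower = cfg@bandPower,
                couplingSpec = cfg@couplingSpec,
                noiseExponent = cfg@noiseExponent,
                noiseVariance = cfg@noiseVariance,
                subjectGainSD = cfg@subjectGainSD,
                bandJitterSD = cfg@bandJitterSD,
                couplingJitterSD = cfg@couplingJitterSD,
                amplitudeJitter = cfg@amplitudeJitter, vasf = cfg@vasf,
                seed = cfg@seed)
  manifest <- list(subjects = sort(unique(cohort@vasf$subject)),
                   conditions = c("pre", "post"), files = as.list(paths),
                   vasf = "vasf.tsv", truth = truth)
  mp <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), mp)
  invisible(mp)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory containing \code{manifest.json}.
#' @return list with \code{recordings} (list of \linkS4class{EEGRecording}),
#'   \code{vasf} (data.frame) and \code{manifest} (the parsed JSON); directly
#'   consumable by \code{\link{runStudy}}.
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  files <- manifest$files
  recs <- lapply(names(files), function(nm)
    readRecording(file.path(dir, sub("\\.tsv$", "", files[[nm]]))))
  names(recs) <- names(files)
  vasf <- utils::read.table(file.path(dir, manifest$vasf), sep = "\t",
                            header = TRUE)
  list(recordings = recs, vasf = vasf, manifest = manifest)
}

#' Write a connectivity matrix as square delimited text
#'
#' Channel labels appear as both header row and first column.
#'
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeConnectivityMatrix <- function(x, path) {
  utils::write.table(weights(x), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read a connectivity matrix written by
#' \code{\link{writeConnectivityMatrix}}
#'
#' @param path file path.
#' @param band,estimator tags to attach (defaults "alpha", "paper_formula").
#' @return a \linkS4class{ConnectivityMatrix}.
#' @export
readConnectivityMatrix <- function(path, band = "alpha",
                                   estimator = "paper_formula") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  new("ConnectivityMatrix", weights = m, band = band, estimator = estimator)
}
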