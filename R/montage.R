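## 56-channel layout constants.
##
## The ten region rows are transcribed verbatim from the study montage tables.
## Their union covers 51 distinct labels; the five labels marked "inferred"
## below (FP1, FPZ, FP2, FT7, FT8) are standard 10-20 extended names added to
## reach the stated 56 retained channels -- they appear only in the full
## channel list, never in a region.
##
## Note the Prefrontal row lists F1, FZ, F2, which also belong to the Frontal
## row. That overlap is kept as printed (likely intended as the FP series);
## montageOverlaps() surfaces it rather than silently renaming.

.REGION_TABLE <- list(
  "prefrontal"        = c("F1", "FZ", "F2"),
  "frontal"           = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8"),
  "fronto-central"    = c("FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6"),
  "central"           = c("C5", "C3", "C1", "CZ", "C2", "C4", "C6"),
  "centro-parietal"   = c("CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6"),
  "parietal"          = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8"),
  "parieto-occipital" = c("PO7", "PO3", "POZ", "PO4", "PO8"),
  "occipital"         = c("O1", "OZ", "O2"),
  "temporal"          = c("T7", "T8"),
  "temporo-parietal"  = c("TP7", "TP8"))

.INFERRED_CHANNELS <- c("FP1", "FPZ", "FP2", "FT7", "FT8")

.CHANNELS_56 <- c(
  "FP1", "FPZ", "FP2",
  "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POZ", "PO4", "PO8",
  "O1", "OZ", "O2")

#' The default 56-channel montage with its ten scalp regions
#'
#' Returns the montage used throughout the pipeline: 56 extended 10-20
#' channel labels in front-to-back order, and the ten region groupings
#' (prefrontal, frontal, fronto-central, central, centro-parietal, parietal,
#' parieto-occipital, occipital, temporal, temporo-parietal) used for
#' local-metric aggregation. Region sizes are 3, 9, 7, 7, 7, 9, 5, 3, 2, 2.
#'
#' The prefrontal region (F1, FZ, F2) overlaps the frontal region as printed
#' in the source tables; see \code{\link{montageOverlaps}}.
#'
#' @param warnOverlap emit a warning describing region overlaps (default
#'   FALSE; the overlap is a documented property of the layout).
#' @return an \linkS4class{EEGMontage}.
#' @examples
#' m <- defaultMontage()
#' regions(m)[["central"]]
#' @export
defaultMontage <- function(warnOverlap = FALSE) {
  m <- new("EEGMontage", channels = .CHANNELS_56, regions = .REGION_TABLE,
           inferred = .INFERRED_CHANNELS)
  if (warnOverlap) {
    ov <- montageOverlaps(m)
    if (nrow(ov))
      warning("montage regions share channels: ",
              paste(unique(ov$channel), collapse = ", "), call. = FALSE)
  }
  m
}

#' Channels shared by more than one region
#'
#' @param montage an \linkS4class{EEGMontage}.
#' @return data.frame with columns \code{channel} and \code{regions} (comma
#'   separated), one row per multiply-assigned channel; zero rows if regions
#'   are disjoint.
#' @export
montageOverlaps <- function(montage) {
  all <- unlist(montage@regions, use.names = FALSE)
  dup <- unique(all[duplicated(all)])
  if (!length(dup))
    return(data.frame(channel = character(), regions = character()))
  data.frame(
    channel = dup,
    regions = vapply(dup, function(ch) {
      paste(names(Filter(function(r) ch %in% r, montage@regions)),
            collapse = ",")
    }, character(1)),
    row.names = NULL)
}

#' @describeIn EEGMontage indices (in recording order) of a region's channels
#' @export
setMethod("regionMask", "EEGMontage", function(x, region) {
  if (!region %in% names(x@regions))
    stop("unknown region '", region, "'; expected one of: ",
         paste(names(x@regions), collapse = ", "))
  match(x@regions[[region]], x@channels)
})

#' Serialize a montage to JSON
#'
#' @param montage an \linkS4class{EEGMontage}.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
montageToJSON <- function(montage, path = NULL) {
  j <- jsonlite::toJSON(list(channels = montage@channels,
                             regions = montage@regions,
                             inferred = montage@inferred),
                        auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(as.character(j))
  writeLines(j, path)
  invisible(as.character(j))
}

#' Read a montage from JSON
#'
#' @param path file path or a JSON string produced by
#'   \code{\link{montageToJSON}}.
#' @return an \linkS4class{EEGMontage}.
#' @export
montageFromJSON <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  new("EEGMontage", channels = as.character(x$channels),
      regions = lapply(x$regions, as.character),
      inferred = as.character(x$inferred))
}
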