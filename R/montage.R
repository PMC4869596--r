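# Channel montage and regions of interest.

#' Construct a channel montage
#'
#' A montage names the recording channels, the reference channels that are
#' averaged and dropped at re-referencing, optional electro-oculogram (EOG)
#' channels used only for artifact rejection, and named regions of interest
#' (ROIs) over the analysis channels.
#'
#' @param recording character vector of recording channel labels (unique)
#' @param reference labels of reference channels (subset of `recording`)
#' @param eog labels of EOG channels (disjoint from `recording`)
#' @param rois named list of character vectors; each ROI must be a subset of
#'   the analysis channels (recording minus reference)
#' @return object of class `montage`
#' @seealso [default_montage()], [analysis_channels()]
#' @export
montage <- function(recording, reference = character(), eog = character(),
                    rois = list()) {
  recording <- as.character(recording)
  if (anyDuplicated(recording)) stop("duplicate recording channel labels")
  if (!all(reference %in% recording)) {
    stop("reference channels not in recording set: ",
         paste(setdiff(reference, recording), collapse = ", "))
  }
  if (any(eog %in% recording)) stop("EOG labels must be distinct from recording labels")
  analysis <- setdiff(recording, reference)
  for (nm in names(rois)) {
    bad <- setdiff(rois[[nm]], analysis)
    if (length(bad)) {
      stop("ROI '", nm, "' contains non-analysis channels: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(recording = recording, reference = as.character(reference),
                 eog = as.character(eog), rois = rois),
            class = "montage")
}

#' The 32-electrode montage used throughout the package examples
#'
#' 30 recording channels in the extended 10-20 layout, re-referenced to the
#' average of the bilateral mastoids (TP9, TP10), leaving 28 analysis
#' channels, plus HEOG/VEOG channels for ocular artifact screening. Two
#' ROIs are predefined: a 14-channel frontal-central set and a 10-channel
#' central-parietal set.
#'
#' @return a [montage()] object
#' @export
default_montage <- function() {
  recording <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
                 "FC1", "FC2", "FC5", "FC6", "C3", "C4", "Cz",
                 "T7", "T8", "CP1", "CP2", "CP5", "CP6",
                 "P3", "P4", "P7", "P8", "Pz", "O1", "O2", "Oz",
                 "TP9", "TP10")
  montage(
    recording = recording,
    reference = c("TP9", "TP10"),
    eog = c("HEOG", "VEOG"),
    rois = list(
      frontal_central = c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "F7", "F8",
                          "Fz", "Cz", "FC1", "FC2", "FC5", "FC6"),
      central_parietal = c("C3", "C4", "P3", "P4", "Cz", "Pz",
                           "CP1", "CP2", "CP5", "CP6")
    )
  )
}

#' Analysis channels of a montage
#'
#' Recording channels minus the reference channels, order preserved.
#'
#' @param m a [montage()] object
#' @return character vector of analysis channel labels
#' @export
analysis_channels <- function(m) {
  stopifnot(inherits(m, "montage"))
  setdiff(m$recording, m$reference)
}

#' @export
print.montage <- function(x, ...) {
  cat("montage:", length(x$recording), "recording channels,",
      length(x$reference), "reference,", length(x$eog), "EOG\n")
  cat("analysis channels:", paste(analysis_channels(x), collapse = " "), "\n")
  for (nm in names(x$rois)) {
    cat("ROI", nm, ":", paste(x$rois[[nm]], collapse = " "), "\n")
  }
  invisible(x)
}

#' Standard frequency bands
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz. Band intervals are treated
#' as half-open `[low, high)` wherever discrete frequency bins are assigned
#' to bands, so shared edges are not double-counted.
#'
#' @return named list of `c(low, high)` pairs in Hz
#' @export
default_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}
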