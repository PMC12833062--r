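#' Default 16-channel clinical montage (10-20 system subset)
#'
#' Frontal, temporal, central, parietal and occipital electrodes of the
#' international 10-20 placement scheme, in the canonical order used for
#' feature naming throughout the package.
#'
#' @return character vector of 16 channel labels.
#' @export
defaultMontage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
    "T3", "T4", "P3", "P4", "T5", "T6", "O1", "O2")
}

#' Canonical EEG frequency bands
#'
#' theta 4-8 Hz, alpha1 8-10 Hz, alpha2 10-13 Hz, beta 13-30 Hz.
#'
#' @return data.frame with columns `name`, `fLow`, `fHigh` (Hz), in canonical
#'   order.
#' @export
defaultBands <- function() {
  data.frame(
    name  = c("theta", "alpha1", "alpha2", "beta"),
    fLow  = c(4, 8, 10, 13),
    fHigh = c(8, 10, 13, 30),
    stringsAsFactors = FALSE
  )
}

checkBands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "fLow", "fHigh") %in% names(bands)))
  if (any(bands$fLow <= 0) || any(bands$fHigh <= bands$fLow))
    stop("band edges must satisfy 0 < fLow < fHigh")
  invisible(bands)
}

#' @describeIn EEGRecording-class channel labels
#' @param x an `EEGRecording`
#' @export
channelLabels <- function(x) rownames(x@data)

#' @describeIn EEGRecording-class sampling frequency in Hz
#' @export
samplingRate <- function(x) x@fs

#' @describeIn EEGRecording-class number of samples per channel
#' @export
nSamples <- function(x) ncol(x@data)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@group, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs))
})

setMethod("show", "EEGEpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EEGEpochSet: %d epochs of %g s (%d channels, %d samples @ %g Hz)\n",
              d[1], object@windowS, d[2], d[3], object@fs))
  cat(sprintf("  subjects: %d (%d DD, %d HC epochs)\n",
              length(unique(object@subjectIds)),
              sum(object@labels == "DD"), sum(object@labels == "HC")))
})

setMethod("show", "GlobalRanking", function(object) {
  cat(sprintf("GlobalRanking (%s aggregation) over %d features\n",
              object@method, length(object@order)))
  top <- object@featureNames[object@order[seq_len(min(5L, length(object@order)))]]
  cat("  top:", paste(top, collapse = ", "), "\n")
})

setMethod("show", "AccuracyCurve", function(object) {
  cat(sprintf("AccuracyCurve: %d subset sizes; optimum %.2f%% at %d features\n",
              length(object@subsetSizes), object@optimumAccuracy, object@optimumSize))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("Leave-one-subject-out evaluation (pooled predictions; positive class: DD)\n")
  cm <- object@confusion
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d (total %d epochs)\n",
              cm["TP"], cm["TN"], cm["FP"], cm["FN"], sum(cm)))
  m <- object@metrics
  cat(sprintf("  accuracy %.2f%% [95%% CI %.2f-%.2f], recall %.2f%%, precision %.2f%%, F1 %.2f%%, AUC %.2f%%\n",
              m["accuracy"], object@ci95[1], object@ci95[2],
              m["recall"], m["precision"], m["f1"], m["auc"]))
  cat(sprintf("  per-subject accuracy: mean %.3f over %d subjects\n",
              mean(object@perSubject), length(object@perSubject)))
})

#' Accessors for evaluation reports
#'
#' @param report an [EvaluationReport-class].
#' @return `confusionCounts()`: named numeric TP/TN/FP/FN; `pooledAccuracy()`:
#'   pooled accuracy in percent; `metricTable()`: one-row data.frame of all
#'   pooled metrics with the CI; `perSubjectAccuracy()`: named numeric vector.
#' @export
confusionCounts <- function(report) report@confusion

#' @rdname confusionCounts
#' @export
pooledAccuracy <- function(report) unname(report@metrics["accuracy"])

#' @rdname confusionCounts
#' @export
metricTable <- function(report) {
  data.frame(as.list(report@metrics),
             ci95_low = report@ci95[1], ci95_high = report@ci95[2])
}

#' @rdname confusionCounts
#' @export
perSubjectAccuracy <- function(report) report@perSubject
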