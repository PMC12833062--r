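#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats fft rnorm runif sd var quantile setNames predict
#' @importFrom utils head write.csv read.csv
NULL

#' Single-subject multichannel EEG recording
#'
#' Container for one subject's multichannel time series together with the
#' sampling rate, channel labels and the subject's group label (`"DD"` for
#' depressive disorder, `"HC"` for healthy control).
#'
#' @slot subjectId character scalar, unique subject identifier.
#' @slot group character scalar, `"DD"` or `"HC"`.
#' @slot fs numeric scalar, sampling frequency in Hz.
#' @slot data numeric matrix, channels x samples; rownames are channel labels.
#'
#' @seealso [EEGRecording()] for the constructor, [generateSubject()].
#' @export
setClass("EEGRecording",
  representation(
    subjectId = "character",
    group     = "character",
    fs        = "numeric",
    data      = "matrix"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
  if (!object@group %in% c("DD", "HC")) msg <- c(msg, "group must be 'DD' or 'HC'")
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (is.null(rownames(object@data))) msg <- c(msg, "data must have channel labels as rownames")
  if (!all(is.finite(object@data))) msg <- c(msg, "data contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param subjectId subject identifier.
#' @param group `"DD"` or `"HC"`.
#' @param fs sampling frequency in Hz.
#' @param data numeric matrix, channels x samples, with channel labels as
#'   rownames (or supplied via `channels`).
#' @param channels optional character vector of channel labels.
#' @return an [EEGRecording-class] object.
#' @export
EEGRecording <- function(subjectId, group, fs, data, channels = rownames(data)) {
  if (!is.null(channels)) rownames(data) <- channels
  new("EEGRecording", subjectId = as.character(subjectId),
      group = as.character(group), fs = as.numeric(fs), data = data)
}

#' Set of fixed-length EEG epochs
#'
#' Non-overlapping windows cut from one or more recordings, stored as a
#' 3-dimensional array `[epoch, channel, sample]` with per-epoch subject
#' identifiers and group labels.
#'
#' @slot epochs numeric array, n_epochs x n_channels x n_window_samples.
#' @slot windowS numeric scalar, window length in seconds.
#' @slot fs numeric scalar, sampling frequency in Hz.
#' @slot subjectIds character vector, one per epoch.
#' @slot labels character vector, one per epoch (`"DD"`/`"HC"`).
#'
#' @export
setClass("EEGEpochSet",
  representation(
    epochs     = "array",
    windowS    = "numeric",
    fs         = "numeric",
    subjectIds = "character",
    labels     = "character"
  )
)

setValidity("EEGEpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-d array [epoch, channel, sample]")
  else {
    if (d[3] != round(object@windowS * object@fs))
      msg <- c(msg, "window sample count must equal windowS * fs")
    if (length(object@subjectIds) != d[1]) msg <- c(msg, "one subjectId per epoch required")
    if (length(object@labels) != d[1]) msg <- c(msg, "one label per epoch required")
  }
  if (!all(object@labels %in% c("DD", "HC"))) msg <- c(msg, "labels must be 'DD' or 'HC'")
  # each subject must carry exactly one label
  tab <- unique(data.frame(s = object@subjectIds, l = object@labels))
  if (anyDuplicated(tab$s)) msg <- c(msg, "a subject maps to more than one label")
  if (length(msg)) msg else TRUE
})

#' Named feature matrix as a SummarizedExperiment
#'
#' Rows are features (power spectral density, sample entropy or phase lag
#' index, per band and channel or channel pair), columns are epochs.
#' `rowData` holds the feature descriptors (`family`, `band`, `channel`,
#' `pair`); `colData` holds per-epoch `subjectId`, `group` and a `synthetic`
#' flag for oversampled rows.
#'
#' @seealso [buildFeatureMatrix()], [featureValues()], [featureInfo()]
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

#' Aggregated global feature ranking
#'
#' @slot order integer permutation of feature indices, best first.
#' @slot method `"modal"` or `"ranksum"`.
#' @slot featureNames character vector, names in original column order.
#' @export
setClass("GlobalRanking",
  representation(order = "integer", method = "character", featureNames = "character")
)

setValidity("GlobalRanking", function(object) {
  n <- length(object@order)
  if (!setequal(object@order, seq_len(n))) return("order must be a permutation of 1..n")
  if (!object@method %in% c("modal", "ranksum")) return("method must be 'modal' or 'ranksum'")
  TRUE
})

#' Accuracy as a function of feature-subset size
#'
#' Result of incremental forward inclusion along a global feature ranking.
#'
#' @slot subsetSizes integer vector of evaluated prefix sizes.
#' @slot accuracies numeric vector, pooled LOSO accuracy (%) per size.
#' @slot optimumSize integer, smallest size attaining the maximum accuracy.
#' @slot optimumAccuracy numeric, the maximum accuracy (%).
#' @export
setClass("AccuracyCurve",
  representation(subsetSizes = "integer", accuracies = "numeric",
                 optimumSize = "integer", optimumAccuracy = "numeric")
)

setValidity("AccuracyCurve", function(object) {
  if (length(object@subsetSizes) != length(object@accuracies))
    return("subsetSizes and accuracies must have equal length")
  if (abs(object@optimumAccuracy - max(object@accuracies)) > 1e-12)
    return("optimumAccuracy must equal max(accuracies)")
  TRUE
})

#' Pooled leave-one-subject-out evaluation report
#'
#' Predictions from every fold are pooled into a single confusion matrix
#' (DD is the positive class) before metrics are computed.
#'
#' @slot confusion named numeric, pooled TP/TN/FP/FN counts.
#' @slot metrics named numeric, accuracy/recall/precision/f1/auc in percent
#'   (`NA` where a denominator is zero).
#' @slot ci95 numeric length-2, binomial-normal 95% CI for accuracy (%).
#' @slot perSubject named numeric, per-subject fraction of epochs correct.
#' @slot predictions data.frame with columns subjectId, truth, predicted,
#'   score (pooled over all folds).
#' @export
setClass("EvaluationReport",
  representation(confusion = "numeric", metrics = "numeric", ci95 = "numeric",
                 perSubject = "numeric", predictions = "data.frame")
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (!setequal(names(object@confusion), c("TP", "TN", "FP", "FN")))
    msg <- c(msg, "confusion must have names TP, TN, FP, FN")
  if (sum(object@confusion) != nrow(object@predictions))
    msg <- c(msg, "confusion total must equal pooled prediction count")
  if (length(msg)) msg else TRUE
})
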