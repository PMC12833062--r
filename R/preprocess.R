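# Preprocessing chain: broadband bandpass -> downsample -> baseline
# correction -> fixed-window segmentation. Per-band rhythm extraction is
# applied later, at the epoch level, inside feature extraction.

#' Zero-phase Butterworth bandpass filter
#'
#' Filters each channel independently with an order-`order` Butterworth
#' bandpass applied forward and backward (`signal::filtfilt`), so the output
#' has zero phase distortion — a prerequisite for unbiased phase-lag-index
#' estimates downstream. The effective magnitude roll-off is therefore that
#' of a filter of twice the design order.
#'
#' @param recording an [EEGRecording-class].
#' @param fLow,fHigh band edges in Hz; must satisfy `0 < fLow < fHigh < fs/2`.
#' @param order filter design order (default 4).
#' @return a filtered [EEGRecording-class] of identical dimensions.
#' @export
bandpass <- function(recording, fLow = 4, fHigh = 30, order = 4) {
  fs <- recording@fs
  if (fLow <= 0 || fHigh <= fLow) stop("band edges must satisfy 0 < fLow < fHigh")
  if (fHigh >= fs / 2)
    stop(sprintf("upper band edge %g Hz is at or above the Nyquist frequency %g Hz", fHigh, fs / 2))
  if (order < 1) stop("filter order must be >= 1")
  bf <- signal::butter(order, c(fLow, fHigh) / (fs / 2), type = "pass")
  out <- recording@data
  for (i in seq_len(nrow(out))) out[i, ] <- signal::filtfilt(bf, recording@data[i, ])
  EEGRecording(recording@subjectId, recording@group, fs, out)
}

# Same filter applied to a plain channels-x-samples matrix (epoch level).
bandpassMatrix <- function(mat, fs, fLow, fHigh, order = 4) {
  if (fHigh >= fs / 2) stop("band edge at/above Nyquist")
  bf <- signal::butter(order, c(fLow, fHigh) / (fs / 2), type = "pass")
  out <- mat
  for (i in seq_len(nrow(mat))) out[i, ] <- signal::filtfilt(bf, mat[i, ])
  out
}

#' Integer-factor downsampling
#'
#' Keeps every `factor`-th sample and divides the sampling rate accordingly.
#' No additional anti-alias filter is applied: the pipeline's preceding
#' 4-30 Hz bandpass already confines the signal well below the new Nyquist
#' frequency, which must remain above 30 Hz.
#'
#' @param recording an [EEGRecording-class].
#' @param factor integer decimation factor (default 2, 250 Hz -> 125 Hz).
#' @return a decimated [EEGRecording-class].
#' @export
downsample <- function(recording, factor = 2) {
  if (factor != round(factor) || factor < 1) stop("factor must be a positive integer")
  newFs <- recording@fs / factor
  if (newFs / 2 < 30)
    stop(sprintf("downsampling to %g Hz puts the Nyquist frequency below the 30 Hz beta edge", newFs))
  idx <- seq(1, ncol(recording@data), by = factor)
  EEGRecording(recording@subjectId, recording@group, newFs,
               recording@data[, idx, drop = FALSE])
}

#' Per-channel baseline (DC offset) correction
#'
#' Subtracts each channel's mean, removing DC drift so every channel is
#' zero-mean.
#'
#' @param recording an [EEGRecording-class].
#' @return the mean-centred [EEGRecording-class].
#' @export
baselineCorrect <- function(recording) {
  out <- recording@data - rowMeans(recording@data)
  EEGRecording(recording@subjectId, recording@group, recording@fs, out)
}

#' Segment a recording into non-overlapping fixed-length epochs
#'
#' Cuts consecutive windows of `windowS` seconds from the start of the
#' recording; a trailing remainder shorter than one window is discarded.
#' Epochs inherit the recording's subject identifier and group label.
#'
#' @param recording an [EEGRecording-class].
#' @param windowS window length in seconds; `windowS * fs` must be integral.
#' @return an [EEGEpochSet-class].
#' @export
segmentRecording <- function(recording, windowS) {
  fs <- recording@fs
  w <- windowS * fs
  if (abs(w - round(w)) > 1e-9) stop("windowS * fs must be an integer number of samples")
  w <- as.integer(round(w))
  n <- ncol(recording@data)
  nEp <- n %/% w
  if (nEp < 1)
    stop(sprintf("recording of %.2f s is shorter than one %g s window", n / fs, windowS))
  ep <- array(0, dim = c(nEp, nrow(recording@data), w))
  for (k in seq_len(nEp)) ep[k, , ] <- recording@data[, ((k - 1) * w + 1):(k * w)]
  new("EEGEpochSet", epochs = ep, windowS = windowS, fs = fs,
      subjectIds = rep(recording@subjectId, nEp),
      labels = rep(recording@group, nEp))
}

#' Combine epoch sets from multiple subjects
#'
#' @param epochSets list of [EEGEpochSet-class] with identical window length,
#'   channel count and sampling rate.
#' @return one pooled [EEGEpochSet-class].
#' @export
combineEpochSets <- function(epochSets) {
  stopifnot(length(epochSets) >= 1)
  d <- dim(epochSets[[1]]@epochs)
  for (es in epochSets) {
    if (!identical(dim(es@epochs)[2:3], d[2:3]) || es@fs != epochSets[[1]]@fs)
      stop("epoch sets differ in channels, window samples or sampling rate")
  }
  total <- sum(vapply(epochSets, function(e) dim(e@epochs)[1], integer(1)))
  ep <- array(0, dim = c(total, d[2], d[3]))
  ids <- character(total); labs <- character(total)
  at <- 0L
  for (es in epochSets) {
    k <- dim(es@epochs)[1]
    ep[at + seq_len(k), , ] <- es@epochs
    ids[at + seq_len(k)] <- es@subjectIds
    labs[at + seq_len(k)] <- es@labels
    at <- at + k
  }
  new("EEGEpochSet", epochs = ep, windowS = epochSets[[1]]@windowS,
      fs = epochSets[[1]]@fs, subjectIds = ids, labels = labs)
}

#' Run the fixed preprocessing chain on one recording
#'
#' Applies, in order: 4-30 Hz zero-phase bandpass, downsampling by `factor`,
#' baseline correction, and segmentation into `windowS`-second epochs. This
#' order is fixed: the broadband filter precedes decimation (acting as the
#' anti-alias stage) and segmentation happens last, so no per-epoch edge
#' effects are introduced at the broadband stage.
#'
#' @param recording an [EEGRecording-class] (raw, e.g. 250 Hz).
#' @param windowS epoch length in seconds (4, 6, 8, 10 or 12 in the standard
#'   protocol).
#' @param fLow,fHigh broadband edges in Hz (default 4 and 30).
#' @param factor decimation factor (default 2).
#' @return an [EEGEpochSet-class].
#' @export
preprocessRecording <- function(recording, windowS, fLow = 4, fHigh = 30, factor = 2) {
  r <- bandpass(recording, fLow, fHigh)
  r <- downsample(r, factor)
  r <- baselineCorrect(r)
  segmentRecording(r, windowS)
}

#' Preprocess every recording of a cohort into one pooled epoch set
#'
#' @param recordings list of [EEGRecording-class].
#' @inheritParams preprocessRecording
#' @return an [EEGEpochSet-class] pooling all subjects' epochs.
#' @export
preprocessCohort <- function(recordings, windowS, fLow = 4, fHigh = 30, factor = 2) {
  combineEpochSets(lapply(recordings, preprocessRecording,
                          windowS = windowS, fLow = fLow, fHigh = fHigh,
                          factor = factor))
}
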