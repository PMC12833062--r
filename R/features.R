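# Three feature families per epoch and band: band-averaged periodogram
# power (PSD), sample entropy (SE) on the band-limited signal, and phase lag
# index (PLI) between channel pairs. For the default 16-channel montage and
# four bands this yields 64 + 64 + 480 = 608 named features.

#' Analytic signal via the FFT half-spectrum method
#'
#' Returns the complex analytic signal `x + i*H(x)` where `H` is the Hilbert
#' transform, computed by zeroing negative frequencies and doubling positive
#' ones in the discrete spectrum.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-averaged periodogram power
#'
#' Computes the plain (rectangular-window) periodogram
#' `Px(f) = |X(f)|^2 / N` and returns its mean over the frequency bins
#' falling inside `[fLow, fHigh]` inclusive — the discrete form of the
#' band-normalised integral `1/(fHigh - fLow) * integral of Px`.
#'
#' @param x numeric vector (a single-channel epoch, already band-limited in
#'   the standard pipeline).
#' @param fs sampling frequency in Hz.
#' @param fLow,fHigh band edges in Hz; must lie within `(0, fs/2]`.
#' @return nonnegative scalar.
#' @export
bandPsd <- function(x, fs, fLow, fHigh) {
  if (fLow <= 0 || fHigh <= fLow) stop("band edges must satisfy 0 < fLow < fHigh")
  if (fHigh > fs / 2) stop("upper band edge above the Nyquist frequency")
  n <- length(x)
  Px <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= fLow & f <= fHigh & f <= fs / 2
  if (!any(keep)) stop("no frequency bins inside the requested band")
  mean(Px[keep])
}

# Full two-sided periodogram (used by tests for the Parseval identity).
periodogram <- function(x, fs) {
  n <- length(x)
  list(freq = (seq_len(n) - 1) * fs / n, power = Mod(stats::fft(x))^2 / n)
}

#' Sample entropy
#'
#' Negative logarithm of the conditional probability that epoch subsequences
#' matching for `m` points (Chebyshev distance strictly below the tolerance
#' `rCoeff * SD(x)`, self-matches excluded) also match for `m + 1`
#' points. Higher values indicate a more irregular signal. Template counting
#' follows the standard Richman-Moorman convention, implemented in C++.
#'
#' @param x numeric vector, length >= 10, non-constant.
#' @param m embedding dimension (default 2).
#' @param rCoeff tolerance as a fraction of the signal SD (default 0.15).
#' @return nonnegative scalar; `Inf` if no template pair matches at length
#'   `m + 1` (perfectly unpredictable at tolerance `r`).
#' @export
sampleEntropy <- function(x, m = 2, rCoeff = 0.15) {
  n <- length(x)
  if (n < 10) stop("series too short for sample entropy (need N >= 10)")
  if (n - m < 2) stop("series too short for m + 1 point templates")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("sample entropy undefined for a constant signal (SD = 0)")
  .sampenCpp(as.numeric(x), as.integer(m), rCoeff * s)
}

#' Phase lag index between two equal-length signals
#'
#' Computes instantaneous phases from the analytic signals, the phase
#' difference `arg(z1 * Conj(z2))`, and `PLI = |mean(sign(dphi))|`. The
#' index lies in `[0, 1]`, is symmetric in its arguments, ignores zero-lag
#' (volume-conduction) coupling, and is invariant to amplitude scaling.
#' 10% of samples at each epoch edge are excluded from the average, where
#' the Hilbert phase estimate is unreliable.
#'
#' @param a,b numeric vectors of equal length (band-limited to the same
#'   band in the standard pipeline).
#' @param edgeTrim fraction of samples dropped at each end (default 0.1).
#' @return scalar in `[0, 1]`.
#' @export
pli <- function(a, b, edgeTrim = 0.1) {
  if (length(a) != length(b)) stop("signals must have equal length")
  n <- length(a)
  dphi <- Arg(analyticSignal(a) * Conj(analyticSignal(b)))
  k <- floor(edgeTrim * n)
  if (k > 0 && n - 2 * k >= 2) dphi <- dphi[(k + 1):(n - k)]
  abs(mean(sign(dphi)))
}

# ---- FeatureSet construction -------------------------------------------

#' Construct a FeatureSet from an epoch x feature value matrix
#'
#' @param values numeric matrix, epochs (rows) x features (columns), with
#'   feature names as colnames.
#' @param descriptors data.frame with columns family, band, channel, pair,
#'   name — one row per feature, in column order.
#' @param labels per-epoch group labels (`"DD"`/`"HC"`).
#' @param subjectIds per-epoch subject identifiers.
#' @param synthetic logical per-epoch flag for oversampled rows.
#' @return a [FeatureSet-class].
#' @export
newFeatureSet <- function(values, descriptors, labels, subjectIds,
                          synthetic = rep(FALSE, nrow(values))) {
  if (!all(is.finite(values))) stop("feature matrix contains non-finite values")
  stopifnot(nrow(descriptors) == ncol(values),
            length(labels) == nrow(values),
            length(subjectIds) == nrow(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)),
    rowData = S4Vectors::DataFrame(descriptors),
    colData = S4Vectors::DataFrame(subjectId = subjectIds, group = labels,
                                   synthetic = synthetic)
  )
  rownames(se) <- descriptors$name
  colnames(se) <- sprintf("epoch%04d", seq_len(nrow(values)))
  new("FeatureSet", se)
}

#' Accessors for FeatureSet objects
#'
#' @param fs a [FeatureSet-class].
#' @return `featureValues()`: numeric matrix, epochs x features;
#'   `featureInfo()`: data.frame of feature descriptors; `epochLabels()` and
#'   `epochSubjects()`: per-epoch character vectors; `isSynthetic()`:
#'   per-epoch logical.
#' @export
featureValues <- function(fs) t(SummarizedExperiment::assay(fs, "features"))

#' @rdname featureValues
#' @export
featureInfo <- function(fs) as.data.frame(SummarizedExperiment::rowData(fs))

#' @rdname featureValues
#' @export
epochLabels <- function(fs) SummarizedExperiment::colData(fs)$group

#' @rdname featureValues
#' @export
epochSubjects <- function(fs) SummarizedExperiment::colData(fs)$subjectId

#' @rdname featureValues
#' @export
isSynthetic <- function(fs) SummarizedExperiment::colData(fs)$synthetic

#' Restrict a FeatureSet to one feature family
#'
#' @param fs a [FeatureSet-class].
#' @param family `"PSD"`, `"SE"` or `"PLI"` (or any family present).
#' @return the row-subset [FeatureSet-class].
#' @export
selectFamily <- function(fs, family) {
  keep <- featureInfo(fs)$family %in% family
  if (!any(keep)) stop("no features of family ", paste(family, collapse = "/"))
  fs[keep, ]
}

setMethod("show", "FeatureSet", function(object) {
  info <- featureInfo(object)
  cat(sprintf("FeatureSet: %d features x %d epochs (%d subjects)\n",
              nrow(object), ncol(object), length(unique(epochSubjects(object)))))
  cat("  families:", paste(sprintf("%s=%d", names(table(info$family)),
                                   table(info$family)), collapse = ", "), "\n")
  labs <- table(epochLabels(object))
  cat("  epochs:", paste(sprintf("%s=%d", names(labs), labs), collapse = ", "),
      sprintf("(synthetic: %d)\n", sum(isSynthetic(object))))
})

# Canonical descriptor table: PSD block, then SE, then PLI; bands in
# canonical order inside each block; channels / pairs in montage order.
featureUniverse <- function(channels, bands = defaultBands()) {
  pairs <- t(utils::combn(channels, 2))
  blocks <- list()
  for (fam in c("PSD", "SE")) {
    for (b in bands$name) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        family = fam, band = b, channel = channels, pair = NA_character_)
    }
  }
  for (b in bands$name) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      family = "PLI", band = b, channel = NA_character_,
      pair = paste(pairs[, 1], pairs[, 2], sep = "-"))
  }
  out <- do.call(rbind, blocks)
  out$name <- ifelse(out$family == "PLI",
                     paste(out$family, out$band, out$pair, sep = "_"),
                     paste(out$family, out$band, out$channel, sep = "_"))
  out
}

#' Canonical feature-name universe
#'
#' All feature names, in canonical column order, for a montage and band set:
#' `FAMILY_band_channel` for PSD and SE, `FAMILY_band_chA-chB` for PLI.
#'
#' @param channels channel labels in montage order.
#' @param bands band definition data.frame.
#' @return character vector of length
#'   `2 * n_channels * n_bands + choose(n_channels, 2) * n_bands`.
#' @export
featureUniverseNames <- function(channels = defaultMontage(), bands = defaultBands()) {
  featureUniverse(channels, bands)$name
}

#' Extract the full multidimensional feature matrix from an epoch set
#'
#' For every epoch and band the channels are band-limited with a 4th-order
#' zero-phase Butterworth filter; then per channel the band PSD and sample
#' entropy are computed, and the PLI for every unordered channel pair.
#' Columns follow the canonical order (PSD block, SE block, PLI block; bands
#' theta, alpha1, alpha2, beta within each; channels/pairs in montage
#' order): 64 + 64 + 480 = 608 features for 16 channels and 4 bands.
#'
#' @param epochSet an [EEGEpochSet-class] (preprocessed).
#' @param bands band definition data.frame as from [defaultBands()].
#' @param channels channel labels in montage order; defaults to the first
#'   `n_channels` labels of [defaultMontage()].
#' @param verbose print progress every 25 epochs.
#' @return a [FeatureSet-class].
#' @export
buildFeatureMatrix <- function(epochSet, bands = defaultBands(),
                               channels = defaultMontage()[seq_len(dim(epochSet@epochs)[2])],
                               verbose = FALSE) {
  checkBands(bands)
  d <- dim(epochSet@epochs)
  nEp <- d[1]; nCh <- d[2]
  if (length(channels) != nCh) stop("channel label count does not match epoch array")
  fs <- epochSet@fs
  desc <- featureUniverse(channels, bands)
  nFeat <- nrow(desc)
  pairs <- t(utils::combn(seq_len(nCh), 2))
  vals <- matrix(NA_real_, nrow = nEp, ncol = nFeat,
                 dimnames = list(NULL, desc$name))
  nB <- nrow(bands)
  for (e in seq_len(nEp)) {
    ep <- epochSet@epochs[e, , , drop = TRUE]
    if (is.null(dim(ep))) ep <- matrix(ep, nrow = 1)
    psd <- matrix(0, nCh, nB); sen <- matrix(0, nCh, nB)
    pliv <- matrix(0, nrow(pairs), nB)
    for (bi in seq_len(nB)) {
      bl <- tryCatch(
        bandpassMatrix(ep, fs, bands$fLow[bi], bands$fHigh[bi]),
        error = function(err) stop("epoch ", e, ", band ", bands$name[bi], ": ",
                                   conditionMessage(err)))
      zs <- matrix(0i, nCh, ncol(bl))
      for (ci in seq_len(nCh)) {
        psd[ci, bi] <- bandPsd(bl[ci, ], fs, bands$fLow[bi], bands$fHigh[bi])
        sen[ci, bi] <- tryCatch(
          sampleEntropy(bl[ci, ]),
          error = function(err) stop("epoch ", e, ", channel ", channels[ci],
                                     ", band ", bands$name[bi], ": ",
                                     conditionMessage(err)))
        zs[ci, ] <- analyticSignal(bl[ci, ])
      }
      n <- ncol(bl); k <- floor(0.1 * n)
      mid <- if (k > 0 && n - 2 * k >= 2) (k + 1):(n - k) else seq_len(n)
      for (pi in seq_len(nrow(pairs))) {
        dphi <- Arg(zs[pairs[pi, 1], mid] * Conj(zs[pairs[pi, 2], mid]))
        pliv[pi, bi] <- abs(mean(sign(dphi)))
      }
    }
    if (any(!is.finite(sen)))
      stop("non-finite sample entropy in epoch ", e,
           " (no template matches at tolerance r)")
    vals[e, ] <- c(as.vector(psd), as.vector(sen), as.vector(pliv))
    if (verbose && e %% 25 == 0) message("  features: epoch ", e, "/", nEp)
  }
  newFeatureSet(vals, desc, epochSet@labels, epochSet@subjectIds)
}

#' Write a FeatureSet to CSV
#'
#' One row per epoch; first columns `subjectId`, `group`, `synthetic`, then
#' the canonical feature columns `FAMILY_band_channel` /
#' `FAMILY_band_chA-chB`.
#'
#' @param fs a [FeatureSet-class].
#' @param path output CSV path.
#' @export
writeFeatureCsv <- function(fs, path) {
  df <- data.frame(subjectId = epochSubjects(fs), group = epochLabels(fs),
                   synthetic = isSynthetic(fs), featureValues(fs),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
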