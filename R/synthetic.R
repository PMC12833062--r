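# Synthetic resting-state EEG cohort with plantable DD-vs-HC group effects:
# a beta-band power shift, a complexity (sample-entropy) shift, and lagged
# phase coupling on designated channel pairs.

#' Synthetic cohort configuration
#'
#' Defines the cohort to simulate: group sizes, montage, sampling rate,
#' recording duration, and the three plantable group effects. Defaults mirror
#' a clinical resting-state cohort: 70 depressive-disorder (DD) subjects and
#' 30 healthy controls (HC), 16 channels of the 10-20 system sampled at
#' 250 Hz.
#'
#' @param nDD,nHC subjects per group (>= 1 each).
#' @param nChannels number of channels; labels come from [defaultMontage()].
#' @param fs sampling frequency in Hz; must exceed twice the highest band
#'   edge (30 Hz).
#' @param duration seconds of signal per subject. 60 s gives at least 5
#'   epochs at every window length from 4 to 12 s.
#' @param betaPowerEffect multiplier on the DD group's beta-band oscillation
#'   amplitude (1 = no effect).
#' @param complexityEffect fraction in `[0, 1)` of DD broadband variance
#'   replaced by a deterministic periodic component, lowering sample entropy
#'   (0 = no effect).
#' @param couplingEffect phase-coupling strength in `[0, 1]` applied to the
#'   DD group's `coupledPairs` (0 = no effect; 1 = the pair carries only the
#'   shared lagged source).
#' @param coupledPairs list of length-2 character vectors of channel labels
#'   receiving the shared phase-lagged source; pairs must be disjoint (no
#'   channel in two pairs).
#' @param couplingBand band (Hz, length 2) of the shared source; default
#'   alpha2, 10-13 Hz.
#' @param phaseLag phase lag (radians) between the two channels of each
#'   coupled pair; default pi/2.
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return a validated `CohortConfig` list.
#' @export
cohortConfig <- function(nDD = 70, nHC = 30, nChannels = 16, fs = 250,
                         duration = 60, betaPowerEffect = 1.5,
                         complexityEffect = 0.2, couplingEffect = 0.5,
                         coupledPairs = list(c("F3", "P3"), c("F4", "P4"),
                                             c("F7", "T5"), c("F8", "T6")),
                         couplingBand = c(10, 13), phaseLag = pi / 2,
                         seed = 1L) {
  if (nDD < 1 || nHC < 1) stop("nDD and nHC must each be >= 1")
  if (fs <= 60) stop("fs must exceed 60 Hz to represent the beta band (13-30 Hz)")
  if (couplingEffect < 0 || couplingEffect > 1) stop("couplingEffect must lie in [0, 1]")
  if (complexityEffect < 0 || complexityEffect >= 1) stop("complexityEffect must lie in [0, 1)")
  if (betaPowerEffect <= 0) stop("betaPowerEffect must be positive")
  channels <- defaultMontage()[seq_len(nChannels)]
  for (p in coupledPairs)
    if (!all(p %in% channels)) stop("coupledPairs must name channels in the montage")
  if (anyDuplicated(unlist(coupledPairs)))
    stop("coupledPairs must be disjoint: a channel cannot belong to two coupled pairs")
  structure(list(nDD = as.integer(nDD), nHC = as.integer(nHC),
                 nChannels = as.integer(nChannels), channels = channels,
                 fs = fs, duration = duration,
                 betaPowerEffect = betaPowerEffect,
                 complexityEffect = complexityEffect,
                 couplingEffect = couplingEffect,
                 coupledPairs = coupledPairs, couplingBand = couplingBand,
                 phaseLag = phaseLag, seed = as.integer(seed)),
            class = "CohortConfig")
}

# Run expr under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so simulation calls do not perturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

subjectSeed <- function(masterSeed, index) {
  as.integer((abs(as.numeric(masterSeed)) * 7919 + index * 104729) %% 2147483647L)
}

# 1/f-shaped background noise via spectral shaping of white noise (unit SD).
pinkNoise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  amp <- 1 / sqrt(pmax(f, 1))                # flat below 1 Hz, 1/f power above
  amp[1] <- 0                                # remove DC
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Band-limited noise (unit SD) by zero-phase Butterworth filtering.
narrowbandNoise <- function(n, fs, fLow, fHigh) {
  bf <- signal::butter(4, c(fLow, fHigh) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, stats::rnorm(n))
  y / stats::sd(y)
}

# Deterministic low-complexity periodic waveform with theta and beta
# harmonics (unit SD); mixing it in lowers sample entropy. Harmonics avoid
# the alpha bands so the waveform (common to all channels, zero lag) cannot
# mask the lagged coupling source planted in the alpha2 band.
periodicComponent <- function(n, fs) {
  t <- (seq_len(n) - 1) / fs
  p <- sin(2 * pi * 6 * t) + 0.6 * sin(2 * pi * 18 * t) +
    0.4 * sin(2 * pi * 24 * t)
  p / stats::sd(p)
}

# Relative oscillation amplitudes of an eyes-closed resting-state spectrum
# (alpha-dominant), on top of unit-SD 1/f background.
bandAmplitudes <- c(theta = 0.4, alpha1 = 0.6, alpha2 = 0.6, beta = 0.35)

#' Simulate one subject's EEG recording
#'
#' Each channel is a sum of 1/f-shaped background noise and band-limited
#' oscillations in theta, alpha1, alpha2 and beta. For DD subjects the beta
#' oscillation amplitude is multiplied by `betaPowerEffect`, a fraction
#' `complexityEffect` of each channel's variance is replaced by a
#' deterministic periodic waveform (lowering sample entropy), and each
#' `coupledPairs` entry receives a shared narrowband source injected into
#' both channels with a fixed `phaseLag`, at variance fraction
#' `couplingEffect`. Deterministic given `(group, config, subjectSeed)`.
#'
#' @param group `"DD"` or `"HC"`.
#' @param config a [cohortConfig()].
#' @param subjectSeed integer seed for this subject.
#' @param subjectId identifier; default derived from group and seed.
#' @return an [EEGRecording-class].
#' @export
generateSubject <- function(group, config, subjectSeed,
                            subjectId = sprintf("%s_%d", group, subjectSeed)) {
  if (!group %in% c("DD", "HC")) stop("group must be 'DD' or 'HC'")
  stopifnot(inherits(config, "CohortConfig"))
  n <- round(config$fs * config$duration)
  chans <- config$channels
  withSeed(subjectSeed, {
    bands <- defaultBands()
    amp <- bandAmplitudes
    if (group == "DD") amp["beta"] <- amp["beta"] * config$betaPowerEffect
    dat <- matrix(0, nrow = length(chans), ncol = n, dimnames = list(chans, NULL))
    for (ci in seq_along(chans)) {
      x <- pinkNoise(n, config$fs)
      for (bi in seq_len(nrow(bands))) {
        x <- x + amp[bands$name[bi]] *
          narrowbandNoise(n, config$fs, bands$fLow[bi], bands$fHigh[bi])
      }
      dat[ci, ] <- x
    }
    if (group == "DD" && config$couplingEffect > 0) {
      # Replace a fraction of each pair channel's coupling-band content with
      # the shared lagged source, leaving the rest of the spectrum (and the
      # band power profile) untouched, so the planted effect is phase
      # coupling rather than a power shift.
      w <- config$couplingEffect
      bf <- signal::butter(4, config$couplingBand / (config$fs / 2), type = "pass")
      for (p in config$coupledPairs) {
        src <- narrowbandNoise(n, config$fs, config$couplingBand[1], config$couplingBand[2])
        z <- analyticSignal(src)
        sA <- Re(z)
        sB <- Re(z * exp(-1i * config$phaseLag))
        for (k in 1:2) {
          s <- if (k == 1) sA else sB
          ch <- p[k]
          part <- signal::filtfilt(bf, dat[ch, ])
          s <- s / stats::sd(s) * stats::sd(part)
          dat[ch, ] <- (dat[ch, ] - part) + sqrt(1 - w) * part + sqrt(w) * s
        }
      }
    }
    if (group == "DD" && config$complexityEffect > 0) {
      c_ <- config$complexityEffect
      per <- periodicComponent(n, config$fs)
      for (ci in seq_along(chans)) {
        dat[ci, ] <- sqrt(1 - c_) * dat[ci, ] + sqrt(c_) * per * stats::sd(dat[ci, ])
      }
    }
    EEGRecording(subjectId, group, config$fs, dat)
  })
}

#' Simulate a labeled cohort with known ground truth
#'
#' Generates `nDD + nHC` recordings with per-subject seeds derived from
#' `config$seed`, plus a ground-truth table of the feature descriptors the
#' generator planted as group-informative: beta-band PSD and beta-band sample
#' entropy on every channel, and PLI in the coupling band on every coupled
#' pair.
#'
#' @param config a [cohortConfig()].
#' @return list with elements `recordings` (list of [EEGRecording-class]) and
#'   `groundTruth` (data.frame with columns family, band, channel, pair, and
#'   canonical feature `name`).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  groups <- c(rep("DD", config$nDD), rep("HC", config$nHC))
  ids <- c(sprintf("DD%02d", seq_len(config$nDD)), sprintf("HC%02d", seq_len(config$nHC)))
  recs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    recs[[i]] <- generateSubject(groups[i], config, subjectSeed(config$seed, i),
                                 subjectId = ids[i])
  }
  names(recs) <- ids
  bands <- defaultBands()
  cb <- bands$name[bands$fLow <= config$couplingBand[1] &
                     bands$fHigh >= config$couplingBand[2]]
  if (length(cb) == 0) cb <- "alpha2"
  gt <- rbind(
    data.frame(family = "PSD", band = "beta", channel = config$channels, pair = NA_character_),
    data.frame(family = "SE", band = "beta", channel = config$channels, pair = NA_character_),
    do.call(rbind, lapply(config$coupledPairs, function(p)
      data.frame(family = "PLI", band = cb[1], channel = NA_character_,
                 pair = paste(sort(p), collapse = "-"))))
  )
  gt$name <- ifelse(gt$family == "PLI",
                    paste(gt$family, gt$band, gt$pair, sep = "_"),
                    paste(gt$family, gt$band, gt$channel, sep = "_"))
  list(recordings = recs, groundTruth = gt)
}

#' Write a cohort to disk as per-subject CSVs plus a JSON manifest
#'
#' Each subject becomes one CSV (rows = samples, columns = channel labels);
#' the manifest records subjectId, group, fs and file name.
#'
#' @param cohort result of [generateCohort()] (or a list of recordings).
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(recs, function(r) {
    f <- paste0(r@subjectId, ".csv")
    utils::write.csv(as.data.frame(t(r@data)), file.path(dir, f), row.names = FALSE)
    list(subjectId = r@subjectId, group = r@group, fs = r@fs, file = f)
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(unname(manifest), mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing per-subject CSVs and `manifest.json`.
#' @return list of [EEGRecording-class] objects.
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    d <- as.matrix(utils::read.csv(file.path(dir, m$file), check.names = FALSE))
    EEGRecording(m$subjectId, m$group, m$fs, t(d), channels = colnames(d))
  })
  names(recs) <- manifest$subjectId
  recs
}

#' Directly simulate an epoch-level feature matrix with planted features
#'
#' Bypasses signal generation: produces a [FeatureSet-class] in which the
#' first `nInformative` features carry a between-group mean shift of `effect`
#' (in within-subject SD units) and the remaining `nNoise` features are pure
#' noise. Epochs from the same subject share a random subject intercept, so
#' leave-one-subject-out structure is respected. Used for feature-selection
#' recovery studies where the signal-processing stage is not under test.
#'
#' @param nDD,nHC subjects per group.
#' @param epochsPerSubject epochs (rows) per subject.
#' @param nInformative,nNoise feature counts.
#' @param effect group mean shift on informative features (default 1.5).
#' @param subjectSD SD of the per-subject random intercept (default 0.5).
#' @param seed integer seed.
#' @return list with `features` (a [FeatureSet-class]) and `planted`
#'   (character vector of planted feature names).
#' @export
plantedFeatureSet <- function(nDD = 10, nHC = 10, epochsPerSubject = 6,
                              nInformative = 5, nNoise = 45, effect = 1.5,
                              subjectSD = 0.5, seed = 1L) {
  withSeed(seed, {
    nFeat <- nInformative + nNoise
    fnames <- sprintf("F%03d", seq_len(nFeat))
    groups <- c(rep("DD", nDD), rep("HC", nHC))
    ids <- c(sprintf("DD%02d", seq_len(nDD)), sprintf("HC%02d", seq_len(nHC)))
    rows <- list(); labs <- character(); subj <- character()
    for (i in seq_along(ids)) {
      intercept <- stats::rnorm(nFeat, sd = subjectSD)
      shift <- if (groups[i] == "DD") c(rep(effect, nInformative), rep(0, nNoise)) else 0
      for (e in seq_len(epochsPerSubject)) {
        rows[[length(rows) + 1L]] <- intercept + shift + stats::rnorm(nFeat)
        labs <- c(labs, groups[i]); subj <- c(subj, ids[i])
      }
    }
    vals <- do.call(rbind, rows)
    colnames(vals) <- fnames
    desc <- data.frame(family = "SYN", band = NA_character_,
                       channel = fnames, pair = NA_character_, name = fnames)
    fs <- newFeatureSet(vals, desc, labs, subj)
    list(features = fs, planted = fnames[seq_len(nInformative)])
  })
}
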