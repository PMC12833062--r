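# Minority-class oversampling by interpolation between nearest neighbours
# (SMOTE-style), used to balance DD vs HC counts inside training folds.

#' Oversampling configuration
#'
#' @param k number of nearest minority neighbours considered per minority
#'   sample (default 5); must be smaller than the minority class size.
#' @param N synthetic repetitions per minority sample, or `"auto"` to reach
#'   class balance.
#' @param purify logical; if `TRUE`, first remove majority samples whose
#'   nearest neighbour (in z-scored feature space) is a minority sample
#'   (Tomek-style cleaning). Default `FALSE`.
#' @param seed integer seed for neighbour and interpolation draws.
#' @return a validated `AugmentConfig` list.
#' @export
augmentConfig <- function(k = 5, N = "auto", purify = FALSE, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (!identical(N, "auto") && (!is.numeric(N) || N < 0 || N != round(N)))
    stop("N must be a nonnegative integer or 'auto'")
  structure(list(k = as.integer(k), N = N, purify = isTRUE(purify),
                 seed = as.integer(seed)), class = "AugmentConfig")
}

# z-score columns with center/scale fit on the same matrix; constant columns
# get unit scale so distances stay finite.
zscoreFit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
zscoreApply <- function(x, fit) sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")

#' Balance classes by nearest-neighbour interpolation
#'
#' For each minority-class sample `X_i`, `N` times: one of its `k` nearest
#' minority neighbours `X_nn` (Euclidean distance on z-scored features) is
#' drawn uniformly, `lambda ~ Uniform[0, 1]`, and the synthetic sample
#' `X_i + lambda * (X_nn - X_i)` is appended with the minority label and a
#' synthetic-subject tag. With `N = "auto"` enough rows are synthesised to
#' equalise the class counts exactly (base repetitions plus a remainder
#' spread over randomly chosen minority samples). Original rows are never
#' modified.
#'
#' The minority class is inferred from the label counts; ties mean the set
#' is already balanced and it is returned unchanged under `N = "auto"`.
#'
#' @param fs a [FeatureSet-class] (typically a training fold).
#' @param config an [augmentConfig()].
#' @param .lambda optional fixed interpolation weight (testing hook);
#'   `NULL` (default) draws `lambda ~ Uniform[0, 1]` per synthetic row.
#' @return a [FeatureSet-class] with synthetic rows appended (flagged by
#'   `isSynthetic()` and subject tag `synth_<parent>_<j>`).
#' @export
ccrBalance <- function(fs, config = augmentConfig(), .lambda = NULL) {
  stopifnot(inherits(config, "AugmentConfig"))
  vals <- featureValues(fs)
  labs <- as.character(epochLabels(fs))
  subj <- as.character(epochSubjects(fs))
  tab <- table(labs)
  if (length(tab) < 2) stop("oversampling requires both classes in the input")
  minority <- names(tab)[which.min(tab)]
  nMin <- min(tab); nMaj <- max(tab)
  if (identical(config$N, "auto") && nMin == nMaj) return(fs)
  if (nMin <= config$k)
    stop(sprintf("minority class size (%d) must exceed k (%d)", nMin, config$k))

  withSeed(config$seed, {
    if (config$purify) {
      z <- zscoreApply(vals, zscoreFit(vals))
      dmat <- as.matrix(stats::dist(z))
      diag(dmat) <- Inf
      nn <- apply(dmat, 1, which.min)
      drop <- labs != minority & labs[nn] == minority
      if (any(drop)) {
        vals <- vals[!drop, , drop = FALSE]
        labs <- labs[!drop]; subj <- subj[!drop]
        fs <- fs[, !drop]
        tab <- table(labs); nMin <- min(tab); nMaj <- max(tab)
      }
    }
    minIdx <- which(labs == minority)
    zfit <- zscoreFit(vals)
    zmin <- zscoreApply(vals[minIdx, , drop = FALSE], zfit)
    dmat <- as.matrix(stats::dist(zmin))
    diag(dmat) <- Inf
    nnIdx <- t(apply(dmat, 1, function(d) order(d)[seq_len(config$k)]))

    if (identical(config$N, "auto")) {
      need <- nMaj - nMin
      reps <- rep(need %/% nMin, nMin)
      extra <- need %% nMin
      if (extra > 0) {
        bump <- sample(nMin, extra)
        reps[bump] <- reps[bump] + 1L
      }
    } else {
      reps <- rep(as.integer(config$N), nMin)
    }

    synth <- list(); synthSubj <- character()
    for (ii in seq_along(minIdx)) {
      i <- minIdx[ii]
      for (j in seq_len(reps[ii])) {
        nn <- minIdx[nnIdx[ii, sample.int(config$k, 1)]]
        lam <- if (is.null(.lambda)) stats::runif(1) else .lambda
        synth[[length(synth) + 1L]] <- vals[i, ] + lam * (vals[nn, ] - vals[i, ])
        synthSubj <- c(synthSubj, sprintf("synth_%s_%d", subj[i], length(synth)))
      }
    }
    if (length(synth) == 0) return(fs)
    newVals <- rbind(vals, do.call(rbind, synth))
    newFeatureSet(newVals, featureInfo(fs),
                  c(labs, rep(minority, length(synth))),
                  c(subj, synthSubj),
                  synthetic = c(isSynthetic(fs), rep(TRUE, length(synth))))
  })
}
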