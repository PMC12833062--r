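# SVM-RFE feature ranking per LOSO fold, cross-fold rank aggregation
# (modal and rank-sum rules), and incremental forward inclusion along the
# aggregated order.

#' Rank features by recursive elimination with a linear SVM
#'
#' Features are z-scored, then a linear-kernel SVM (`C = 1`) is fit
#' repeatedly; at every round the `step` features with the smallest absolute
#' margin weight `|w|` are eliminated and assigned the worst outstanding
#' ranks (the last survivor gets rank 1). Weight-magnitude ranking requires
#' the linear kernel even when classification elsewhere uses the RBF kernel.
#' Ties in `|w|` are eliminated in ascending column order, so among exact
#' duplicates the lower-index column receives the worse rank.
#'
#' @param values numeric matrix, samples x features (or a
#'   [FeatureSet-class]).
#' @param labels per-sample `"DD"`/`"HC"` labels (ignored when `values` is a
#'   `FeatureSet`).
#' @param step features eliminated per round (default 1).
#' @return integer vector: rank of each feature (1 = most important), a
#'   permutation of `1..n_features`.
#' @export
svmRfeRank <- function(values, labels = NULL, step = 1) {
  if (is(values, "FeatureSet")) {
    labels <- as.character(epochLabels(values))
    values <- featureValues(values)
  }
  if (length(unique(labels)) < 2) stop("both classes required for SVM-RFE")
  if (step < 1) stop("step must be >= 1")
  x <- zscoreApply(values, zscoreFit(values))
  y <- factor(labels, levels = c("HC", "DD"))
  n <- ncol(x)
  remaining <- seq_len(n)
  ranks <- integer(n)
  nextWorst <- n
  while (length(remaining) > 0) {
    if (length(remaining) == 1) {
      ranks[remaining] <- 1L
      break
    }
    m <- e1071::svm(x[, remaining, drop = FALSE], y, kernel = "linear",
                    cost = 1, scale = FALSE)
    w <- drop(t(m$coefs) %*% m$SV)
    k <- min(step, length(remaining) - 1)
    worst <- order(abs(w))[seq_len(k)]           # ties: lower index first
    for (idx in worst) {
      ranks[remaining[idx]] <- nextWorst
      nextWorst <- nextWorst - 1L
    }
    remaining <- remaining[-worst]
  }
  names(ranks) <- colnames(x)
  ranks
}

#' Per-fold SVM-RFE rankings across all LOSO iterations
#'
#' Runs [svmRfeRank()] once per leave-one-subject-out training fold (one
#' iteration per subject, so a 100-subject cohort yields a 100 x n ranking
#' matrix). Each row sees only its training fold's epochs.
#'
#' @param fs a [FeatureSet-class].
#' @param step elimination step passed to [svmRfeRank()].
#' @param verbose print progress.
#' @return integer matrix, iterations x features; each row a permutation of
#'   `1..n_features`. Rownames are held-out subject ids, colnames feature
#'   names.
#' @export
rankFeaturesLoso <- function(fs, step = 1, verbose = FALSE) {
  subj <- as.character(epochSubjects(fs))
  subjects <- unique(subj)
  out <- matrix(NA_integer_, nrow = length(subjects), ncol = nrow(fs),
                dimnames = list(subjects, rownames(fs)))
  for (fi in seq_along(subjects)) {
    train <- fs[, subj != subjects[fi]]
    out[fi, ] <- svmRfeRank(featureValues(train),
                            as.character(epochLabels(train)), step = step)
    if (verbose) message("  RFE ranking: fold ", fi, "/", length(subjects))
  }
  out
}

checkRankingMatrix <- function(rankings) {
  n <- ncol(rankings)
  ok <- apply(rankings, 1, function(r) setequal(r, seq_len(n)))
  if (!all(ok)) stop("every ranking-matrix row must be a permutation of 1..n")
  invisible(rankings)
}

#' Aggregate per-fold rankings by modal top-position frequency
#'
#' Position `p` of the global order is filled with the not-yet-selected
#' feature that appears most frequently within rank positions `1..p` across
#' all iterations; ties are broken by smaller rank sum, then by smaller
#' feature index.
#'
#' @param rankings integer matrix, iterations x features (rows are
#'   permutations; 1 = best).
#' @return a [GlobalRanking-class] with `method = "modal"`.
#' @export
aggregateModal <- function(rankings) {
  checkRankingMatrix(rankings)
  n <- ncol(rankings)
  rs <- colSums(rankings)
  counts <- numeric(n)            # occurrences within top-p, updated per p
  selected <- logical(n)
  ord <- integer(n)
  for (p in seq_len(n)) {
    counts <- counts + colSums(rankings == p)
    cand <- which(!selected)
    best <- cand[order(-counts[cand], rs[cand], cand)][1]
    ord[p] <- best
    selected[best] <- TRUE
  }
  fn <- colnames(rankings)
  if (is.null(fn)) fn <- sprintf("feature%d", seq_len(n))
  new("GlobalRanking", order = ord, method = "modal", featureNames = fn)
}

#' Aggregate per-fold rankings by rank summation
#'
#' Features are ordered by ascending column-wise rank sum; ties are broken
#' by smaller feature index.
#'
#' @inheritParams aggregateModal
#' @return a [GlobalRanking-class] with `method = "ranksum"`.
#' @export
aggregateRanksum <- function(rankings) {
  checkRankingMatrix(rankings)
  rs <- colSums(rankings)
  ord <- order(rs, seq_along(rs))
  fn <- colnames(rankings)
  if (is.null(fn)) fn <- sprintf("feature%d", ncol(rankings))
  new("GlobalRanking", order = as.integer(ord), method = "ranksum", featureNames = fn)
}

#' Incremental forward inclusion along a global ranking
#'
#' For each prefix size `s` the full leave-one-subject-out evaluation is run
#' on the top-`s` features and the pooled accuracy recorded. The optimum is
#' the smallest prefix attaining the maximum accuracy.
#'
#' @param fs a [FeatureSet-class].
#' @param ranking a [GlobalRanking-class] covering the features of `fs`.
#' @param classifier a [classifierConfig()].
#' @param augment an [augmentConfig()] or `NULL`.
#' @param cap largest prefix size evaluated (default: all features).
#' @param stride evaluate sizes `1, 1+stride, 1+2*stride, ...` up to `cap`
#'   (default 1, every size); the cap itself is always evaluated.
#' @param seed passed to [runLoso()].
#' @param verbose print progress.
#' @return an [AccuracyCurve-class].
#' @export
forwardInclusion <- function(fs, ranking, classifier = classifierConfig("SVM"),
                             augment = NULL, cap = nrow(fs), stride = 1,
                             seed = 1L, verbose = FALSE) {
  stopifnot(is(ranking, "GlobalRanking"))
  if (length(ranking@order) != nrow(fs))
    stop("ranking does not cover the feature matrix")
  cap <- min(cap, nrow(fs))
  sizes <- unique(c(seq(1, cap, by = stride), cap))
  ordNames <- ranking@featureNames[ranking@order]
  acc <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    rep_ <- runLoso(fs, classifier, augment, seed = seed,
                    features = ordNames[seq_len(sizes[i])])
    acc[i] <- pooledAccuracy(rep_)
    if (verbose) message("  forward inclusion: size ", sizes[i], " acc ",
                         round(acc[i], 2), "%")
  }
  best <- which(acc == max(acc))[1]
  new("AccuracyCurve", subsetSizes = as.integer(sizes), accuracies = acc,
      optimumSize = as.integer(sizes[best]), optimumAccuracy = max(acc))
}

#' Full selection stage: per-fold RFE, aggregation, forward inclusion
#'
#' @param fs a [FeatureSet-class].
#' @param method aggregation rule, `"modal"` (default) or `"ranksum"`.
#' @param step RFE elimination step.
#' @param cap,stride forwarded to [forwardInclusion()].
#' @param classifier,augment,seed forwarded to [forwardInclusion()].
#' @param verbose print progress.
#' @return list with `rankings` (iterations x features matrix), `ranking`
#'   (a [GlobalRanking-class]), `curve` (an [AccuracyCurve-class]) and
#'   `optimalFeatures` (character vector).
#' @export
selectFeatures <- function(fs, method = c("modal", "ranksum"), step = 1,
                           cap = nrow(fs), stride = 1,
                           classifier = classifierConfig("SVM"),
                           augment = NULL, seed = 1L, verbose = FALSE) {
  method <- match.arg(method)
  rankings <- rankFeaturesLoso(fs, step = step, verbose = verbose)
  ranking <- if (method == "modal") aggregateModal(rankings) else aggregateRanksum(rankings)
  curve <- forwardInclusion(fs, ranking, classifier, augment, cap = cap,
                            stride = stride, seed = seed, verbose = verbose)
  optimal <- ranking@featureNames[ranking@order[seq_len(curve@optimumSize)]]
  list(rankings = rankings, ranking = ranking, curve = curve,
       optimalFeatures = optimal)
}
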