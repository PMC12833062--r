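# Strict leave-one-subject-out evaluation: every epoch of the held-out
# subject forms the test fold; scaling and oversampling are fit on the
# training fold only; predictions are pooled across folds into one
# confusion matrix. DD is the positive class throughout.

#' Classifier configuration with fixed hyperparameters
#'
#' Fixed, deterministic configurations: SVM with RBF kernel, `C = 1` and
#' variance-adaptive `gamma = 1 / (n_features * var(X))`; KNN with `k = 5`
#' and uniform votes; random forest with 100 trees and Gini impurity;
#' XGBoost with 100 rounds at learning rate 0.1. The `LGBM` and `CAT` kinds
#' are recognised but have no backend in this package and error at fit time.
#'
#' @param kind one of `"SVM"`, `"KNN"`, `"RF"`, `"XGB"`, `"LGBM"`, `"CAT"`.
#' @return a `ClassifierConfig` list.
#' @export
classifierConfig <- function(kind = c("SVM", "KNN", "RF", "XGB", "LGBM", "CAT")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "ClassifierConfig")
}

# Fit on scaled training data and score the scaled test rows.
# Returns list(pred = character DD/HC, score = numeric, larger => more DD).
fitPredict <- function(clf, xTrain, yTrain, xTest) {
  y <- factor(yTrain, levels = c("HC", "DD"))
  if (clf$kind == "SVM") {
    g <- 1 / (ncol(xTrain) * stats::var(as.vector(xTrain)))
    if (!is.finite(g) || g <= 0) g <- 1 / ncol(xTrain)
    m <- e1071::svm(xTrain, y, kernel = "radial", cost = 1, gamma = g, scale = FALSE)
    pr <- stats::predict(m, xTest, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # decision values are oriented towards the class named first in the colname
    pos <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
    score <- if (pos == "DD") dv else -dv
    list(pred = as.character(pr), score = as.numeric(score))
  } else if (clf$kind == "KNN") {
    pr <- class::knn(xTrain, xTest, y, k = 5, prob = TRUE)
    p <- attr(pr, "prob")
    score <- ifelse(pr == "DD", p, 1 - p)
    list(pred = as.character(pr), score = as.numeric(score))
  } else if (clf$kind == "RF") {
    m <- randomForest::randomForest(xTrain, y, ntree = 100)
    p <- stats::predict(m, xTest, type = "prob")[, "DD"]
    list(pred = ifelse(p >= 0.5, "DD", "HC"), score = as.numeric(p))
  } else if (clf$kind == "XGB") {
    dtr <- xgboost::xgb.DMatrix(xTrain, label = as.numeric(y == "DD"))
    m <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          eta = 0.1, nthread = 1),
                            data = dtr, nrounds = 100, verbose = 0)
    p <- stats::predict(m, xgboost::xgb.DMatrix(xTest))
    list(pred = ifelse(p >= 0.5, "DD", "HC"), score = as.numeric(p))
  } else {
    stop(sprintf("classifier kind '%s' has no backend in this package", clf$kind))
  }
}

#' Pooled confusion metrics
#'
#' Accuracy, precision, recall and F1 (percent) from pooled TP/TN/FP/FN
#' counts, with DD as the positive class: `accuracy = (TP+TN)/total`,
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`. A zero denominator yields `NA` with a warning,
#' never a silent zero.
#'
#' @param confusion named numeric with elements TP, TN, FP, FN.
#' @return named numeric (percent): accuracy, precision, recall, f1.
#' @export
pooledMetrics <- function(confusion) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(confusion)))
  if (any(confusion < 0)) stop("confusion counts must be nonnegative")
  tot <- sum(confusion)
  if (tot == 0) stop("empty confusion matrix")
  tp <- confusion[["TP"]]; tn <- confusion[["TN"]]
  fp <- confusion[["FP"]]; fn <- confusion[["FN"]]
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  c(accuracy = 100 * (tp + tn) / tot,
    precision = ratio(tp, tp + fp, "precision"),
    recall = ratio(tp, tp + fn, "recall"),
    f1 = ratio(2 * tp, 2 * tp + fp + fn, "F1"))
}

#' Binomial-normal confidence interval for an accuracy
#'
#' Normal approximation `p +/- z * sqrt(p(1-p)/n)`, reported in percent and
#' clipped to `[0, 100]`.
#'
#' @param correct number of correct predictions.
#' @param total total predictions (> 0).
#' @param level confidence level (default 0.95).
#' @return numeric length 2: lower and upper bound in percent.
#' @export
accuracyCi <- function(correct, total, level = 0.95) {
  if (total <= 0) stop("total must be positive")
  if (correct < 0 || correct > total) stop("correct must lie in [0, total]")
  p <- correct / total
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / total)
  100 * c(max(0, p - half), min(1, p + half))
}

#' Per-subject accuracy from pooled predictions
#'
#' @param predictions data.frame with columns `subjectId`, `truth`,
#'   `predicted` (as in an [EvaluationReport-class]).
#' @param subjects subjects to report; defaults to all present. An unknown
#'   subject identifier is an error.
#' @return named numeric vector of per-subject fractions correct in `[0, 1]`.
#' @export
subjectAccuracy <- function(predictions, subjects = unique(predictions$subjectId)) {
  unknown <- setdiff(subjects, predictions$subjectId)
  if (length(unknown))
    stop("unknown subject id(s): ", paste(unknown, collapse = ", "))
  vapply(stats::setNames(subjects, subjects), function(s) {
    rows <- predictions$subjectId == s
    mean(predictions$predicted[rows] == predictions$truth[rows])
  }, numeric(1))
}

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: all of that subject's epochs are held out; the
#' z-score scaler and (optionally) the oversampler are fit on the training
#' fold only; the classifier is fit and the held-out epochs predicted.
#' Predictions are pooled over all folds into a single confusion matrix
#' (positive class DD), from which accuracy, precision, recall, F1, AUC
#' (from pooled decision scores) and the binomial-normal 95% CI are derived,
#' along with per-subject accuracies.
#'
#' @param fs a [FeatureSet-class]; every epoch must carry a subject id, and
#'   each class needs at least two subjects.
#' @param classifier a [classifierConfig()] (default SVM).
#' @param augment an [augmentConfig()] applied to each training fold, or
#'   `NULL` for none.
#' @param seed integer; per-fold seeds for oversampling and any stochastic
#'   learner are derived from it.
#' @param features optional character vector restricting the evaluation to a
#'   feature subset (by canonical name).
#' @param foldInfo if `TRUE`, attach per-fold bookkeeping (held-out subject,
#'   training subjects, synthetic-row count) as attribute `"folds"` of the
#'   report, for leakage audits.
#' @return an [EvaluationReport-class].
#' @export
runLoso <- function(fs, classifier = classifierConfig("SVM"), augment = NULL,
                    seed = 1L, features = NULL, foldInfo = FALSE) {
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(fs))
    if (length(missing)) stop("unknown feature(s): ", paste(head(missing, 5), collapse = ", "))
    fs <- fs[features, ]
  }
  subj <- as.character(epochSubjects(fs))
  labs <- as.character(epochLabels(fs))
  subjects <- unique(subj)
  subjLab <- vapply(subjects, function(s) labs[match(s, subj)], character(1))
  perClass <- table(subjLab)
  if (length(perClass) < 2 || any(perClass < 2)) {
    bad <- names(perClass)[perClass < 2]
    stop("need at least two subjects per class; a training fold would lack class ",
         paste(bad, collapse = ", "), " (subjects: ",
         paste(subjects[subjLab %in% bad], collapse = ", "), ")")
  }
  vals <- featureValues(fs)
  preds <- vector("list", length(subjects))
  folds <- vector("list", length(subjects))
  for (fi in seq_along(subjects)) {
    s <- subjects[fi]
    testRows <- subj == s
    trainFs <- fs[, !testRows]
    if (!is.null(augment)) {
      aug <- augment
      aug$seed <- as.integer((as.numeric(seed) * 131 + fi) %% 2147483647)
      trainFs <- ccrBalance(trainFs, aug)
    }
    if (foldInfo) {
      trainSubj <- as.character(epochSubjects(trainFs))
      folds[[fi]] <- list(heldOut = s,
                          trainSubjects = unique(trainSubj[!isSynthetic(trainFs)]),
                          syntheticTags = trainSubj[isSynthetic(trainFs)])
    }
    xTrain <- featureValues(trainFs)
    yTrain <- as.character(epochLabels(trainFs))
    sc <- zscoreFit(xTrain)
    xTrain <- zscoreApply(xTrain, sc)
    xTest <- zscoreApply(vals[testRows, , drop = FALSE], sc)
    set.seed(as.integer((as.numeric(seed) * 977 + fi) %% 2147483647))
    out <- fitPredict(classifier, xTrain, yTrain, xTest)
    preds[[fi]] <- data.frame(subjectId = s, truth = labs[testRows],
                              predicted = out$pred, score = out$score,
                              stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  confusion <- c(
    TP = sum(predictions$truth == "DD" & predictions$predicted == "DD"),
    TN = sum(predictions$truth == "HC" & predictions$predicted == "HC"),
    FP = sum(predictions$truth == "HC" & predictions$predicted == "DD"),
    FN = sum(predictions$truth == "DD" & predictions$predicted == "HC"))
  metrics <- suppressWarnings(pooledMetrics(confusion))
  auc <- tryCatch({
    r <- pROC::roc(response = factor(predictions$truth, levels = c("HC", "DD")),
                   predictor = predictions$score, levels = c("HC", "DD"),
                   direction = "<", quiet = TRUE)
    100 * as.numeric(pROC::auc(r))
  }, error = function(e) NA_real_)
  metrics <- c(metrics, auc = auc)
  ci <- accuracyCi(confusion[["TP"]] + confusion[["TN"]], sum(confusion))
  out <- new("EvaluationReport", confusion = confusion, metrics = metrics,
             ci95 = ci, perSubject = subjectAccuracy(predictions),
             predictions = predictions)
  if (foldInfo) attr(out, "folds") <- folds
  out
}
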