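test_that("pooled metrics follow the confusion-matrix formulas", {
  m <- pooledMetrics(c(TP = 50, TN = 40, FP = 5, FN = 5))
  expect_equal(unname(m["accuracy"]), 90)
  expect_equal(unname(m["precision"]), 100 * 50 / 55, tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 100 * 50 / 55, tolerance = 1e-12)
  expect_equal(unname(m["f1"]), 100 * 100 / 110, tolerance = 1e-12)

  perfect <- pooledMetrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_true(all(perfect == 100))

  expect_warning(m0 <- pooledMetrics(c(TP = 0, TN = 10, FP = 0, FN = 2)),
                 "precision")
  expect_true(is.na(m0[["precision"]]))
  expect_error(pooledMetrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("binomial-normal CI matches the closed form and clips", {
  ci <- accuracyCi(90, 100)
  expect_equal(ci, c(90 - 5.879892, 90 + 5.879892), tolerance = 1e-4)
  expect_equal(accuracyCi(100, 100), c(100, 100))
  expect_equal(accuracyCi(0, 50)[1], 0)
  # interval always contains the point estimate
  for (k in c(1, 25, 49)) {
    ci <- accuracyCi(k, 50)
    expect_true(ci[1] <= 100 * k / 50 && 100 * k / 50 <= ci[2])
  }
  expect_error(accuracyCi(5, 0), "total")
  expect_error(accuracyCi(7, 5), "correct")
})

test_that("per-subject accuracy aggregates pooled predictions correctly", {
  pred <- data.frame(
    subjectId = rep(c("a", "b"), c(6, 4)),
    truth = rep("DD", 10),
    predicted = c(rep("DD", 5), "HC", rep("DD", 2), rep("HC", 2)))
  acc <- subjectAccuracy(pred)
  expect_equal(unname(acc["a"]), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(acc["b"]), 0.5)
  expect_error(subjectAccuracy(pred, subjects = c("a", "zz")), "unknown")
  # epoch-weighted mean of per-subject accuracies equals pooled accuracy
  set.seed(3)
  pred2 <- data.frame(
    subjectId = sample(letters[1:5], 60, replace = TRUE),
    truth = sample(c("DD", "HC"), 60, replace = TRUE),
    predicted = sample(c("DD", "HC"), 60, replace = TRUE))
  acc2 <- subjectAccuracy(pred2)
  w <- table(pred2$subjectId)[names(acc2)]
  expect_equal(sum(acc2 * w) / sum(w), mean(pred2$truth == pred2$predicted),
               tolerance = 1e-12)
})

test_that("LOSO partitions epochs: each subject tested exactly once", {
  p <- plantedFeatureSet(nDD = 3, nHC = 3, epochsPerSubject = 4,
                         nInformative = 3, nNoise = 5, seed = 10)
  rep_ <- runLoso(p$features, seed = 1)
  pred <- rep_@predictions
  expect_equal(nrow(pred), 24)
  expect_equal(sort(table(pred$subjectId)), sort(table(epochSubjects(p$features))))
  expect_equal(sum(confusionCounts(rep_)), 24)
  expect_true(all(rep_@perSubject >= 0 & rep_@perSubject <= 1))
  expect_true(rep_@ci95[1] <= pooledAccuracy(rep_) &&
                pooledAccuracy(rep_) <= rep_@ci95[2])
})

test_that("LOSO rejects cohorts where a training fold would lack a class", {
  p <- plantedFeatureSet(nDD = 1, nHC = 3, epochsPerSubject = 2,
                         nInformative = 2, nNoise = 2, seed = 1)
  expect_error(runLoso(p$features), "two subjects per class")
})

test_that("fold bookkeeping: held-out subjects never enter training", {
  p <- plantedFeatureSet(nDD = 3, nHC = 4, epochsPerSubject = 3,
                         nInformative = 2, nNoise = 4, effect = 2, seed = 5)
  rep_ <- runLoso(p$features, augment = augmentConfig(k = 2), seed = 2,
                  foldInfo = TRUE)
  folds <- attr(rep_, "folds")
  expect_length(folds, 7)
  allSubjects <- unique(as.character(epochSubjects(p$features)))
  for (f in folds) {
    expect_false(f$heldOut %in% f$trainSubjects)
    expect_setequal(f$trainSubjects, setdiff(allSubjects, f$heldOut))
    # synthetic rows interpolate training-fold parents only
    if (length(f$syntheticTags))
      expect_false(any(grepl(paste0("synth_", f$heldOut, "_"), f$syntheticTags)))
  }
  # the scaler is fit per fold: poisoning the held-out subject's rows must
  # not change that subject's own fold model, so its scores shift only
  # through the poisoned inputs while every fold's training stays disjoint.
  expect_setequal(vapply(folds, `[[`, character(1), "heldOut"), allSubjects)
})

test_that("all implemented classifier kinds run; absent backends refuse", {
  p <- plantedFeatureSet(nDD = 3, nHC = 3, epochsPerSubject = 3,
                         nInformative = 3, nNoise = 3, effect = 3, seed = 7)
  for (kind in c("SVM", "KNN", "RF", "XGB")) {
    rep_ <- runLoso(p$features, classifierConfig(kind), seed = 1)
    expect_s4_class(rep_, "EvaluationReport")
    expect_gte(pooledAccuracy(rep_), 50)
  }
  expect_error(runLoso(p$features, classifierConfig("LGBM")), "backend")
  expect_error(classifierConfig("MLP"), "arg")
})

test_that("LOSO is deterministic given the seed", {
  p <- plantedFeatureSet(nDD = 3, nHC = 3, epochsPerSubject = 3,
                         nInformative = 2, nNoise = 6, seed = 4)
  a <- runLoso(p$features, augment = augmentConfig(k = 2), seed = 9)
  b <- runLoso(p$features, augment = augmentConfig(k = 2), seed = 9)
  expect_identical(a@predictions, b@predictions)
  expect_identical(a@metrics, b@metrics)
})

test_that("oversampling is a near-no-op on a balanced cohort", {
  p <- plantedFeatureSet(nDD = 6, nHC = 6, epochsPerSubject = 6,
                         nInformative = 5, nNoise = 8, effect = 2.5, seed = 6)
  accNone <- pooledAccuracy(runLoso(p$features, seed = 3))
  accCcr <- pooledAccuracy(runLoso(p$features, augment = augmentConfig(k = 3),
                                   seed = 3))
  expect_lt(abs(accNone - accCcr), 5)
})

test_that("feature-subset evaluation restricts to the named features", {
  p <- plantedFeatureSet(nDD = 3, nHC = 3, epochsPerSubject = 3,
                         nInformative = 2, nNoise = 4, seed = 8)
  rep_ <- runLoso(p$features, features = c("F001", "F002"), seed = 1)
  expect_equal(nrow(rep_@predictions), 18)
  expect_error(runLoso(p$features, features = "nope"), "unknown feature")
})
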