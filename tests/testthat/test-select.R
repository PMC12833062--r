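separableToy <- function(n = 20, seed = 42) {
  set.seed(seed)
  x1 <- c(rnorm(n / 2, mean = 3, sd = 0.5), rnorm(n / 2, mean = -3, sd = 0.5))
  x2 <- rnorm(n)
  vals <- cbind(informative = x1, noise = x2)
  labels <- rep(c("DD", "HC"), each = n / 2)
  list(vals = vals, labels = labels)
}

test_that("SVM-RFE ranks a perfectly separating feature first", {
  toy <- separableToy()
  ranks <- svmRfeRank(toy$vals, toy$labels)
  expect_equal(ranks[["informative"]], 1L)
  expect_setequal(ranks, 1:2)
})

test_that("SVM-RFE always returns a permutation and rejects one class", {
  set.seed(8)
  vals <- matrix(rnorm(30 * 7), 30, 7)
  labels <- sample(rep(c("DD", "HC"), c(14, 16)))
  for (step in c(1, 2, 3)) {
    r <- svmRfeRank(vals, labels, step = step)
    expect_setequal(r, 1:7)
  }
  expect_error(svmRfeRank(vals, rep("DD", 30)), "both classes")
})

test_that("duplicated features take adjacent ranks under the tie rule", {
  toy <- separableToy(n = 30)
  vals <- cbind(a = toy$vals[, 1], b = toy$vals[, 1], n = toy$vals[, 2])
  ranks <- svmRfeRank(vals, toy$labels)
  # the duplicate pair must occupy consecutive ranks, lower index worse
  expect_equal(abs(ranks[["a"]] - ranks[["b"]]), 1)
  expect_gt(ranks[["a"]], ranks[["b"]])
})

test_that("modal aggregation reproduces the brute-force rule on a 3x3 case", {
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
  colnames(m) <- c("f1", "f2", "f3")
  g <- aggregateModal(m)
  # position 1: f1 appears at rank 1 twice, f2 once -> f1
  expect_equal(g@order[1], 1L)
  # position 2 (ranks <= 2): counts f1=3(sel), f2=2, f3=1 -> f2; f3 last
  expect_equal(g@order, c(1L, 2L, 3L))

  # unanimity: identical rows reproduce that row
  u <- rbind(c(2, 3, 1), c(2, 3, 1), c(2, 3, 1))
  expect_equal(aggregateModal(u)@order, c(3L, 1L, 2L))

  # row order is irrelevant
  expect_equal(aggregateModal(m[c(3, 1, 2), ])@order, g@order)

  expect_error(aggregateModal(rbind(c(1, 1, 3))), "permutation")
})

test_that("rank-sum aggregation orders by column sums with index ties", {
  m <- rbind(c(1, 2), c(2, 1))
  expect_equal(aggregateRanksum(m)@order, c(1L, 2L))  # tie -> smaller index
  u <- rbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(aggregateRanksum(u)@order, c(2L, 3L, 1L))
})

test_that("modal and rank-sum agree on unanimous matrices", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    row <- sample(n)
    m <- matrix(rep(row, 5), nrow = 5, byrow = TRUE)
    expect_equal(aggregateModal(m)@order, aggregateRanksum(m)@order,
                 label = sprintf("unanimous case %d", i))
  }
})

test_that("per-fold rankings never see the held-out subject", {
  p <- plantedFeatureSet(nDD = 3, nHC = 3, epochsPerSubject = 2,
                         nInformative = 2, nNoise = 4, seed = 2)
  fs <- p$features
  rk <- rankFeaturesLoso(fs)
  expect_equal(nrow(rk), 6)            # one iteration per subject
  expect_identical(rownames(rk), unique(as.character(epochSubjects(fs))))
  # poison one subject's rows: only that subject's fold row may stay the same
  vals <- featureValues(fs)
  subj <- as.character(epochSubjects(fs))
  vals[subj == "DD01", ] <- vals[subj == "DD01", ] + 100
  fs2 <- newFeatureSet(vals, featureInfo(fs), as.character(epochLabels(fs)), subj)
  rk2 <- rankFeaturesLoso(fs2)
  expect_identical(rk["DD01", ], rk2["DD01", ])
})

test_that("forward inclusion tracks the curve contract", {
  p <- plantedFeatureSet(nDD = 4, nHC = 4, epochsPerSubject = 3,
                         nInformative = 2, nNoise = 6, effect = 2, seed = 3)
  g <- aggregateRanksum(rankFeaturesLoso(p$features))
  curve <- forwardInclusion(p$features, g, cap = 8)
  expect_length(curve@accuracies, 8)
  expect_equal(curve@subsetSizes, 1:8)
  expect_equal(curve@optimumAccuracy, max(curve@accuracies))
  expect_equal(curve@accuracies[curve@subsetSizes == curve@optimumSize],
               curve@optimumAccuracy)
  # stride skips sizes but always evaluates the cap
  c2 <- forwardInclusion(p$features, g, cap = 8, stride = 3)
  expect_equal(c2@subsetSizes, c(1L, 4L, 7L, 8L))
})

test_that("ground-truth recovery: planted features end up in the optimum", {
  p <- plantedFeatureSet(nDD = 10, nHC = 10, epochsPerSubject = 6,
                         nInformative = 5, nNoise = 45, seed = 1)
  res <- selectFeatures(p$features, method = "modal")
  expect_lte(res$curve@optimumSize, 15)
  expect_gte(mean(p$planted %in% res$optimalFeatures), 0.8)
})

test_that("planted features out-rank null features in aggregated order", {
  p <- plantedFeatureSet(nDD = 8, nHC = 8, epochsPerSubject = 4,
                         nInformative = 5, nNoise = 45, seed = 21)
  g <- aggregateModal(rankFeaturesLoso(p$features))
  pos <- match(p$planted, g@featureNames[g@order])
  nullPos <- setdiff(seq_along(g@order), pos)
  expect_lt(mean(pos), mean(nullPos))
  # one-sided permutation p-value for the mean planted position
  set.seed(1)
  perm <- replicate(2000, mean(sample(seq_along(g@order), length(pos))))
  expect_lt(mean(perm <= mean(pos)), 0.01)
})
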