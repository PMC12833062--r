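test_that("subject generation is deterministic and validates inputs", {
  cfg <- cohortConfig(nDD = 2, nHC = 2, duration = 10, seed = 3)
  a <- generateSubject("HC", cfg, 1)
  b <- generateSubject("HC", cfg, 1)
  expect_identical(a@data, b@data)
  expect_false(identical(a@data, generateSubject("HC", cfg, 2)@data))
  expect_error(generateSubject("XX", cfg, 1), "group")
  expect_error(cohortConfig(fs = 50), "60 Hz")
  expect_error(cohortConfig(nDD = 0), "nDD")
  expect_error(cohortConfig(couplingEffect = 1.2), "couplingEffect")
  expect_error(cohortConfig(coupledPairs = list(c("F3", "P3"), c("F3", "P4"))),
               "disjoint")
})

test_that("recording dimensions, labels and finiteness match the config", {
  cfg <- cohortConfig(nDD = 1, nHC = 1, nChannels = 8, fs = 250,
                      duration = 12, coupledPairs = list(c("F3", "C3")),
                      seed = 9)
  r <- generateSubject("DD", cfg, 4)
  expect_equal(dim(r@data), c(8, 250 * 12))
  expect_identical(channelLabels(r), defaultMontage()[1:8])
  expect_true(all(is.finite(r@data)))
})

test_that("cohort generation counts groups and is reproducible", {
  cfg <- cohortConfig(nDD = 7, nHC = 3, duration = 8, seed = 21)
  co <- generateCohort(cfg)
  expect_length(co$recordings, 10)
  groups <- vapply(co$recordings, function(r) r@group, character(1))
  expect_equal(sum(groups == "DD"), 7)
  co2 <- generateCohort(cfg)
  expect_identical(co$recordings[[5]]@data, co2$recordings[[5]]@data)
  # ground truth covers beta PSD/SE everywhere plus coupled-pair PLI
  gt <- co$groundTruth
  expect_setequal(unique(gt$family), c("PSD", "SE", "PLI"))
  expect_equal(sum(gt$family == "PSD"), 16)
  expect_equal(sum(gt$family == "PLI"), length(cfg$coupledPairs))
  universe <- featureUniverseNames()
  expect_true(all(gt$name %in% universe))
})

test_that("uncoupled channel pairs show near-zero PLI over many seeds", {
  cfg <- cohortConfig(nDD = 1, nHC = 1, duration = 60, couplingEffect = 0,
                      complexityEffect = 0, seed = 1)
  bf <- signal::butter(4, c(10, 13) / (250 / 2), type = "pass")
  vals <- vapply(1:20, function(s) {
    r <- generateSubject("DD", cfg, s)
    pli(signal::filtfilt(bf, r@data["F3", ]),
        signal::filtfilt(bf, r@data["P3", ]))
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
})

test_that("full coupling with quarter-cycle lag yields PLI near 1", {
  cfg <- cohortConfig(nDD = 1, nHC = 1, duration = 30, couplingEffect = 1,
                      complexityEffect = 0, phaseLag = pi / 2, seed = 2)
  r <- generateSubject("DD", cfg, 77)
  # Hilbert-phase oracle on the coupling-band pair, independent of pli()
  bf <- signal::butter(4, c(10, 13) / (250 / 2), type = "pass")
  a <- signal::filtfilt(bf, r@data["F3", ])
  b <- signal::filtfilt(bf, r@data["P3", ])
  dphi <- oraclePhase(a) - oraclePhase(b)
  dphi <- atan2(sin(dphi), cos(dphi))
  n <- length(dphi); keep <- (n %/% 10):(n - n %/% 10)
  expect_gt(abs(mean(sign(dphi[keep]))), 0.9)
  expect_gt(pli(a, b), 0.9)
})

test_that("group beta-power separation grows with the planted effect", {
  betaPower <- function(effect, seeds) {
    cfg <- cohortConfig(nDD = 1, nHC = 1, duration = 20,
                        betaPowerEffect = effect, complexityEffect = 0,
                        couplingEffect = 0, seed = 1)
    bf <- signal::butter(4, c(13, 30) / (250 / 2), type = "pass")
    diffs <- vapply(seeds, function(s) {
      dd <- generateSubject("DD", cfg, s)
      hc <- generateSubject("HC", cfg, s + 1000)
      bandPsd(signal::filtfilt(bf, dd@data[1, ]), 250, 13, 30) -
        bandPsd(signal::filtfilt(bf, hc@data[1, ]), 250, 13, 30)
    }, numeric(1))
    mean(diffs)
  }
  seeds <- 1:10
  d <- vapply(c(1, 1.5, 2.5), betaPower, numeric(1), seeds = seeds)
  expect_true(all(diff(d) > 0))
  expect_lt(abs(d[1]), abs(d[3]))
})

test_that("cohort round-trips through CSV + manifest on disk", {
  cfg <- cohortConfig(nDD = 1, nHC = 1, nChannels = 4, duration = 4,
                      coupledPairs = list(c("F3", "F4")), seed = 8)
  co <- generateCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_length(back, 2)
  expect_equal(back[["DD01"]]@data, co$recordings[["DD01"]]@data,
               tolerance = 1e-12)
  expect_identical(back[["HC01"]]@group, "HC")
})

test_that("planted feature sets carry the advertised structure", {
  p <- plantedFeatureSet(nDD = 4, nHC = 4, epochsPerSubject = 3,
                         nInformative = 5, nNoise = 45, seed = 1)
  expect_s4_class(p$features, "FeatureSet")
  expect_equal(dim(p$features), c(50, 24))
  expect_length(p$planted, 5)
  # planted columns separate groups; noise columns do not
  v <- featureValues(p$features)
  labs <- epochLabels(p$features)
  gap <- colMeans(v[labs == "DD", ]) - colMeans(v[labs == "HC", ])
  expect_gt(min(gap[1:5]), max(abs(gap[6:50])) - 0.5)
  p2 <- plantedFeatureSet(nDD = 4, nHC = 4, epochsPerSubject = 3,
                          nInformative = 5, nNoise = 45, seed = 1)
  expect_identical(featureValues(p$features), featureValues(p2$features))
})
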