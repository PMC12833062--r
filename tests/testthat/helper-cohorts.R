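# Shared simulated fixtures, built lazily once per test run and cached, so
# several test files can reuse the expensive feature extractions.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Strong planted effects: doubled beta amplitude, 0.8 phase coupling.
strongFeatures <- function() fixture("strong", function() {
  cfg <- cohortConfig(nDD = 8, nHC = 8, betaPowerEffect = 2,
                      couplingEffect = 0.8, seed = 11)
  co <- generateCohort(cfg)
  buildFeatureMatrix(preprocessCohort(co$recordings, windowS = 10))
})

# Coupling-dominated: only the phase-coupling effect differs between groups.
couplingFeatures <- function() fixture("coupling", function() {
  cfg <- cohortConfig(nDD = 8, nHC = 8, betaPowerEffect = 1,
                      complexityEffect = 0, couplingEffect = 0.8, seed = 12)
  co <- generateCohort(cfg)
  buildFeatureMatrix(preprocessCohort(co$recordings, windowS = 10))
})

# All effects neutral: the two groups are exchangeable by construction.
nullFeatures <- function() fixture("null", function() {
  cfg <- cohortConfig(nDD = 10, nHC = 10, betaPowerEffect = 1,
                      complexityEffect = 0, couplingEffect = 0, seed = 13)
  co <- generateCohort(cfg)
  buildFeatureMatrix(preprocessCohort(co$recordings, windowS = 10))
})

# Small 4-channel cohort for structural checks (fast).
tinyFeatures <- function() fixture("tiny", function() {
  cfg <- cohortConfig(nDD = 2, nHC = 2, nChannels = 4, duration = 20,
                      coupledPairs = list(c("F3", "F4")), seed = 5)
  co <- generateCohort(cfg)
  buildFeatureMatrix(preprocessCohort(co$recordings, windowS = 10),
                     channels = defaultMontage()[1:4])
})

# Relabel a FeatureSet's groups at the subject level (for permutation nulls).
relabelSubjects <- function(fs, newLabels) {
  subj <- as.character(epochSubjects(fs))
  SummarizedExperiment::colData(fs)$group <- as.character(newLabels[subj])
  fs
}

subjectLabelMap <- function(fs) {
  subj <- unique(as.character(epochSubjects(fs)))
  labs <- as.character(epochLabels(fs))
  setNames(vapply(subj, function(s)
    labs[match(s, as.character(epochSubjects(fs)))], character(1)), subj)
}
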