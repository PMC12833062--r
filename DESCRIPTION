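Package: eegClassify
Title: Multidimensional Resting-State EEG Features for Depression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based classification of depressive disorder from
    multichannel resting-state EEG. Implements band power spectral density,
    sample entropy and phase lag index feature extraction over configurable
    epoch lengths, SMOTE-style minority oversampling, SVM-RFE feature ranking
    with cross-fold rank aggregation and incremental forward inclusion, and
    strict leave-one-subject-out evaluation with pooled confusion metrics.
    Includes a synthetic EEG cohort generator with plantable group effects
    (band power, signal complexity, phase coupling) for calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    class,
    randomForest,
    xgboost,
    pROC,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
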