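Package: gsatpipe
Title: Simulation and Classification of Sustained-Attention EEG Under Chronic Hypoxia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end analysis pipeline for Go/No-Go sustained-attention EEG
    studies comparing chronic high-altitude (hypoxic) and low-altitude groups.
    Generates seeded synthetic two-group EEG cohorts with configurable
    sustained-potential (SP) and band-power group effects; epochs, baseline
    corrects and artifact-screens single-channel recordings; extracts 12
    time-domain SP features and 24 short-time-Fourier-transform event-related
    spectral perturbation (ERSP) features; selects features by the intersection
    of ReliefF and GainRatio rankings; and evaluates SVM, logistic-regression
    and decision-tree classifiers under leave-one-out cross-validation with
    accuracy, F1, sensitivity, specificity, Wald confidence intervals and
    ROC/AUC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
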