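Package: vfmdi
Title: Multi-Domain Prediction of Ventricular Fibrillation Defibrillation
    Outcomes from Short Pre-Shock ECG Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the success of defibrillation countershocks
    in ventricular fibrillation (VF) from short (9 second) pre-shock ECG
    segments, optionally augmented with end-tidal CO2.  Implements adaptive
    Savitzky-Golay preprocessing, delay-coordinate phase-space reconstruction
    with a Rosenstein-style maximal Lyapunov exponent, quasi-period density /
    prototype-distance (QPD-PD) features with an exponential-kernel density
    and a class-separation criterion for parameter selection, dual-tree
    complex wavelet and time-domain descriptors, the amplitude spectrum area
    (AMSA) baseline, statistically validated dimensionality reduction
    (ANOVA, Kruskal-Wallis, Hotelling T-squared), and twice-nested
    cross-validated machine-learning classification with wrapper feature
    selection.  A synthetic VF cohort generator provides labelled test-beds
    with class-dependent dominant frequency, amplitude, organization,
    baseline artifacts and optional capnography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    rpart,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    deSolve,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
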