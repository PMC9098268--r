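Package: echotexture
Title: Texture Radiomics and Classifier Evaluation for Echocardiographic ROIs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided analysis of grayscale echocardiographic regions of
    interest for detecting pacing-induced myocardial change. Implements a
    250-feature texture battery in nine groups (histogram, autoregressive
    model, gradient, histograms of oriented gradients, Gabor magnitudes, Haar
    wavelet subband energies, gray-level run-length and co-occurrence
    statistics, and local binary pattern variants), Kolmogorov-Smirnov and
    t-test gating with Relief-F feature ranking, and a cross-validated
    multi-classifier evaluation harness (decision tree, RBF support vector
    machine, random forest, AdaBoost) with leave-one-out training metrics and
    held-out test metrics. Includes a speckle-image cohort simulator with a
    controllable oriented-band class effect for end-to-end validation when
    clinical images are unavailable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    rpart,
    e1071,
    ranger,
    nortest,
    png,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
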