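Package: visbrix
Title: Qualitative and Quantitative Assessment of Fruit Soluble Solids from
    Visible Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometrics pipeline for grading and predicting fruit soluble
    solid content (SSC, degrees Brix) from visible-range absorbance spectra.
    Provides six spectral pretreatments (standard normal variate, vector
    normalisation, Savitzky-Golay smoothing, first and second derivatives,
    and their combination), principal component feature extraction with
    contribution-rate component selection, SMOTE minority-class
    augmentation, a from-scratch three-layer back-propagation network with
    four nonlinear learning-rate decay schedules, particle swarm
    optimisation of the network weights, a NIPALS partial least squares
    regression baseline, evaluation metrics, and a Lambert-Beer synthetic
    spectra generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    pROC
Config/testthat/edition: 3
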