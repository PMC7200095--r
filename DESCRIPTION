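Package: accbehav
Title: Behaviour Classification from Burst-Mode Tri-Axial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers discrete behaviours of free-ranging animals from
    burst-mode tri-axial acceleration data. Provides moving-window
    augmentation of fixed-length bursts, a fixed predictor set (per-axis
    moments, posture angles, overall dynamic body acceleration and full
    FFT magnitude spectra), three classifier back-ends (radial-kernel
    support vector machine, random forest, feed-forward neural network)
    with a probability-threshold rejection class and burst-level
    absolute-majority voting, window-size selection from smoothed
    performance curves, and four indirect field-validation procedures
    based on GPS clusters, GPS speed, diel behaviour composition and
    actograms. A synthetic-data module generates labelled captive-style
    bursts and wild-style burst/GPS streams with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    randomForest,
    mgcv,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
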