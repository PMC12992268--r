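Package: tdnirs
Title: Time-Domain fNIRS Hemodynamic Pattern Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multichannel time-domain functional
    near-infrared spectroscopy (TD-fNIRS) recordings of block-design
    cognitive tasks. Implements the closed-form time-resolved diffuse
    reflectance of a semi-infinite homogeneous medium, delay-gate
    integration of photon time-of-flight histograms, per-delay modified
    Beer-Lambert oxyhemoglobin changes, diffusion-model task-rest HbO
    ratios from delay-gate pairs, channel quality rejection, separation of
    activated and suppressive hemodynamic responses, integral and centroid
    feature extraction, t-test feature selection, test-retest session
    comparison, and low-dimensional visualized classifiers (linear SVM,
    linear discriminant analysis, shallow decision trees, Gaussian naive
    Bayes) with stratified five-fold cross-validation. Includes a
    synthetic-cohort generator that emulates verbal-fluency-task
    recordings at either the photon-histogram or hemodynamic level.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
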