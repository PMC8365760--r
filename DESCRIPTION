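Package: scenedegrade
Title: Spatial-Frequency Degradation of Natural Scenes and
    Psychometric Comparison of Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying visual categorization under controlled
    image degradation. Implements frequency-domain stimulus operators
    (low- and high-pass spatial-frequency filters with a parabolic
    falloff over three octaves, weighted mean phase scrambling,
    spectral whitening, and luminance standardization), maximum
    likelihood fitting of Weibull psychometric functions with
    parametric bootstrap confidence intervals for the 80% accuracy
    threshold, and ratio-of-proportions statistics (accuracy ratio and
    image-level agreement ratio with Katz log-method intervals and
    Bonferroni correction) for comparing two classifiers such as human
    observers and convolutional networks. A synthetic-data module
    generates 1/f two-category images, simulated Weibull observers
    with controllable image-level error correlation, and a
    spectral-feature stand-in classifier, so the full pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    png,
    rlang,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
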