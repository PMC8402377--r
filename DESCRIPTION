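Package: biaslens
Title: Saliency-Based Bias Detection for Medical Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects shortcut learning (spurious-artifact bias) in image
    classifiers by running seven saliency/attribution methods in tandem --
    LIME over SLIC superpixels, Squaregrid, RISE, GradCAM, and Vanilla,
    Smooth and Integrated Gradients -- and scoring how much heatmap mass each
    method places inside known artifact regions. Ships a synthetic CT-scan-like
    benchmark generator that plants class-correlated artifacts (annotation
    letters, colored markings, hue tints, round frames, support structures)
    with per-artifact ground-truth masks, analytic region-oracle classifiers
    for method validation, a compact trainable convolutional network with
    exact gradients, exhaustive softmax-averaging ensemble search with a
    fewest-members tie-break, and localization/enrichment reporting with
    per-technique heatmap rendering conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
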