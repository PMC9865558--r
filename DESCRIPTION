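Package: lightspd
Title: Light-Source Spectrum Optimization for Machine Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Designs the spectral power distribution (SPD) of a multi-LED
    light source to maximize the performance of a downstream machine-vision
    classifier. Implements a linear per-pixel color observation model that
    renders camera images under arbitrary mixtures of sub-light SPDs, two
    optimizers of the mixture weights (an alternating linear-SVM scheme and
    a neural network in which the lighting weights form a trainable
    rendering layer), a synthetic generator of labeled reflectance cubes
    emulating oral/dental spectral imagery, and evaluation tools:
    one-vs-rest F1 cross-validation, optimal-SPD reconstruction, and
    Mahalanobis interclass-distance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
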