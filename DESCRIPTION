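Package: voitex
Title: Volumetric Texture Features and Gravitational Search Feature
    Selection for Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a 77-dimensional volumetric texture descriptor
    (centroid-line gray-level distribution, gray-level co-occurrence and
    run-length statistics over the 13 unique 3D directions) from masked
    regions of interest in 3D scalar images, selects discriminative
    feature subsets with a refined gravitational search algorithm that
    simultaneously tunes the hyperparameters of a radial-basis support
    vector machine, and evaluates classifiers with leave-one-out
    cross-validation, ROC analysis and paired nonparametric tests.
    Includes a synthetic phantom generator with controlled texture
    contrast so the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
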