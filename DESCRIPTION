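Package: multiplexcore
Title: Core-Periphery Analysis of Multimodal Multiplex Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multimodal multiplex brain networks from morphological
    covariance, structural and functional connectivity layers, extracts the
    rich-core decomposition over a density-threshold sweep to obtain nodal
    coreness, and quantifies global core-periphery weakening with the
    coreness disruption index (kappa). Includes empirical-Bayes location and
    scale harmonization of multi-site features, permutation-based group
    statistics with false discovery rate control and bootstrap effect sizes,
    bagged decision-tree prediction of clinical status with out-of-bag
    permutation feature importance, and a synthetic cohort generator with
    planted core-periphery structure and targeted hub attack for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
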