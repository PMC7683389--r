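Package: ssforest
Title: Graph-Embedded Semi-Supervised Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised random forests for partially labeled tabular and
    image-derived data. A kNN Gaussian affinity graph is built over labeled and
    unlabeled points, labels are propagated by a closed-form graph-regularized
    least-squares solve, and the resulting pseudo-labels replace the
    split-selection (stage 3) information gain of an oblique random forest with
    a graph-embedded Gini gain. Includes oracle forest variants for
    bottleneck-style experiments, accuracy-curve harnesses, patch and Gabor
    wavelet feature extraction for vessel-like images, and synthetic
    manifold-structured data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    readr,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    class,
    optparse,
    yaml
Config/testthat/edition: 3
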