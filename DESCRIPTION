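Package: wbmfs
Title: Wrapper-Based Metaheuristic Feature Selection for Deep-Feature
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection over banks of deep-feature tables
    using eight population-based binary metaheuristics (marine predators,
    atom search, Harris hawks, butterfly, whale, grey wolf, bat and
    firefly algorithms). Candidate feature subsets are scored by a
    support-vector-machine wrapper cost that trades validation error
    against subset size. Includes a network-selection-and-concatenation
    pipeline, per-class confusion-matrix metrics, an extreme-point
    cropping preprocessor for grayscale brain MRI, synthetic feature-bank
    and image generators, and an exhaustive-search oracle for validating
    the optimizers at small dimensionality.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
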