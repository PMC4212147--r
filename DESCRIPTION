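Package: simdex
Title: Combined Chemical Similarity Index for Read-Across Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a generalizable chemical similarity index that blends a
    binary fingerprint similarity with three non-binary structural keys built
    from constitutional molecular descriptors (constitutional, hetero-atom and
    functional-group keys), weighted under a unit-sum constraint. Provides nine
    fingerprint families (hashed path fingerprints and structural-key
    families), registries of 44 binary and 6 non-binary similarity
    coefficients, a 3-nearest-neighbour similarity-weighted read-across
    predictor with leave-one-out validation, and a two-stage combinatorial
    evaluation engine (fingerprint x coefficient, then weight scheme x
    coefficient) ranked by desirability and utility functions. Molecule
    handling is delegated to ChemmineR/ChemmineOB (Open Babel).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
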