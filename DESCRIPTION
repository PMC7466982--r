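Package: hypoxpanel
Title: Discovery and Validation of Temperature-Robust Hypoxia Gene-Expression Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering stressor-specific gene-expression
    biomarkers that are robust to a confounding factor, built around the
    hypoxia-versus-temperature problem in salmonid gill transcriptomics.
    Provides negative-binomial count modelling with paired within-temperature
    contrasts, direction-consistent intersection of differential-expression
    lists, PCA-axis correlation ranking with confounder-axis exclusion,
    delta-delta-Ct qPCR quantification with amplification-efficiency and
    reference-gene stability estimation, and validation of small biomarker
    panels by nearest-shrunken-centroid gene selection and linear discriminant
    analysis on stratified train/test splits. Includes a synthetic-data
    generator with planted effects so every stage can be checked against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
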