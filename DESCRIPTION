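Package: imtx
Title: Imaging Transcriptomics of Brain Function and Perfusion Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Links group differences in resting-state low-frequency
    fluctuation amplitude (ALFF) and arterial-spin-labeling cerebral blood
    flow (CBF) maps to regional gene expression. Provides voxelwise
    covariate-adjusted group contrasts with Gaussian-random-field cluster
    correction, donor-level expression aggregation with inter-donor
    stability filtering, first-component partial-least-squares (PLS1)
    spatial association with permutation and bootstrap inference,
    hypergeometric over-representation analysis of the selected gene sets,
    and a fully seeded synthetic-cohort generator so every stage can be
    validated by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
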