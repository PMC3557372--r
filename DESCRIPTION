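Package: tickniche
Title: Climate-Niche Quantification for Tick Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying the climate niches
    of ixodid ticks (and other vector species) from curated occurrence
    records. Provides record validation and harmonization against a study
    window and synonym tables, attachment of gridded monthly environmental
    covariates (land surface temperature, NDVI, rainfall) by nearest-cell
    lookup, construction of a reduced climate space by principal components
    analysis, kernel-smoothed occupancy densities on a climate-space grid,
    Schoener's D niche overlap with a permutation test of niche equivalency,
    unsupervised k-means habitat classification from seasonal covariate
    profiles, hexagonal geographic binning, and a synthetic-data generator
    with known niche structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
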