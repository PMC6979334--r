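Package: photrait
Title: Photosynthetic Trait Derivation from Leaf Gas Exchange and
    Chlorophyll Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives leaf photosynthetic traits from combined gas-exchange
    and chlorophyll-fluorescence records: electron transport rate from PSII
    operating efficiency, mesophyll conductance by the variable-J method
    with a dCc/dA quality criterion, one-point maximum carboxylation rate,
    and intrinsic water-use efficiency.  Fits nonrectangular-hyperbola
    light-response curves by orthogonal least squares and derives the
    light-saturated rate, light compensation point and saturating light.
    A coupled Farquhar-von Caemmerer-Berry leaf simulator generates
    synthetic instrument records and F2-like trait populations so every
    stage can be validated by parameter recovery, and population-level
    summaries (trait distributions, normality tests, correlations, group
    contrasts) plus a seeded end-to-end pipeline support phenotyping
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
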