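Package: taxatime
Title: Temporal Turnover and Environmental Drivers of Microbial Community
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies temporal dynamics of microbial communities sampled as
    count-table time series, such as monthly 16S amplicon surveys of activated
    sludge bioreactors. Implements taxa-time relationship (TTR) accumulation
    curves and power-law fitting (S = c*T^w), per-phylum turnover exponents
    with dominant-versus-rare contrasts, moving-window community-change
    statistics, Pearson and Sorenson similarity matrices, canonical
    correspondence analysis (CCA) built from the chi-square eigen-formulation,
    Monte Carlo forward selection of covariates, and three-way variance
    partitioning of explained inertia. Includes read quality filtering,
    seeded rarefaction, taxonomic rank collapsing, richness summaries, and a
    calibrated synthetic community generator so every stage is testable
    without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
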