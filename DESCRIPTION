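Package: bethedgr
Title: Evolutionarily Stable Germination Strategies for Desert Annuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling bet-hedging germination strategies of
    Sonoran Desert winter annuals. Fits a two-stage hurdle model relating
    per-germinant seed yield to precipitation, embeds it in a
    density-dependent stochastic seed-bank model, solves for the
    evolutionarily stable germination fraction (ESS) of each species by
    invasion analysis, and regresses germination fractions on standardized
    life-history traits. Includes a synthetic-data generator for
    precipitation series, observation tables, and whole communities so the
    full pipeline can be exercised and calibrated without external data.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
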