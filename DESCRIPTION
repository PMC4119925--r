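Package: lethaldose
Title: Lethal-Dose Estimation for Microbial Stress-Tolerance Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates median and decile lethal doses (LD50, LD10) from
    colony-count stress-tolerance assays in which the initial inoculum is
    unknown. Counts are modelled with a negative binomial regression that
    combines strain and experiment fixed effects with a penalized B-spline
    (P-spline) smooth of square-root dose per strain; lethal doses are
    obtained by inverting the fitted survival curve and parametric-bootstrap
    percentile intervals quantify uncertainty in LD values and in
    between-strain LD differences. Includes a synthetic assay generator with
    shoulder-shaped survival curves and known true lethal doses, minimum
    inhibitory concentration (MIC) determination from growth/no-growth
    tables, and two-panel dose-response reporting figures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    patchwork,
    purrr,
    Rcpp,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
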