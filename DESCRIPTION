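Package: heatpm
Title: Case-Crossover Analysis of Temperature and PM2.5 Synergism in
    Heat-Related Hospitalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating the independent and joint short-term
    effects of daily maximum temperature and 3-day mean fine particulate
    matter (PM2.5) on heat-related hospitalization using a time-stratified
    case-crossover design.  Provides a synthetic data generator with a
    fully known hazard, bidirectional same-month same-weekday referent
    selection, exposure windowing with percentile trimming, Bayesian and
    maximum-likelihood conditional logistic regression with natural cubic
    spline exposure-response curves and a linear or tensor-product
    interaction, and additive-scale interaction summaries (relative excess
    risk due to interaction, RERI) with 95% credible intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
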