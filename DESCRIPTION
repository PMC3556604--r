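Package: o3hia
Title: Ozone-Related Health Impacts of Climate Change on a Grid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale health impact assessment pipeline for climate-driven
    changes in surface ozone. Implements the log-linear concentration-response
    health impact function on gridded seasonal-mean MDA8 ozone fields,
    age-structured population allocation, county baseline incidence rates with
    life-table projection, metric conversion and inverse-variance pooling of
    concentration-response coefficients, a factorial ensemble over modeling
    systems, population projections and epidemiological studies with balanced
    ANOVA variance decomposition, population-weighted exposure-change
    distributions, and a synthetic-data generator that emulates the inputs so
    the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    knitr,
    jsonlite,
    optparse
Config/testthat/edition: 3
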