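Package: mbrfit
Title: Automated Growth-Rate Determination from Microbioreactor Backscatter Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates maximum specific growth rates from high-throughput
    microbioreactor (e.g. 48-well BioLector) backscatter time series. The
    blank and the additive measurement error are estimated from pre-growth
    readings, the exponential growth phase is detected by iterative removal
    of trailing measurements under three stopping criteria (adjusted R-squared
    threshold, accelerating biomass increase, non-negative increases), and the
    growth rate is obtained by weighted linear regression on log-transformed
    blanked biomass, with a weighted non-linear exponential regression
    cross-check. Includes plate-scale batch processing, replicate aggregation,
    comparison against reference growth rates, and a synthetic growth-curve
    simulator (lag, exponential, diauxic and stationary phases) with known
    ground truth.
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
    minpack.lm,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
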