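Package: saltoil
Title: Oilseed Yield Modelling and Biofuel Feasibility on Salt-Affected Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Crop yield response models for oilseed mustard grown on
    marginally productive saline soils (Maas-Hoffman two-piece salt
    tolerance, three-piece and quadratic boron tolerance, and a full
    polynomial regression on root-zone salinity, boron, leaching fraction
    and water content), model fitting with backward t-score screening,
    regional Monte Carlo simulation of biofuel production under input
    uncertainty, and shifted-gamma feasibility statistics with exceedance
    probabilities against a production target. Includes synthetic-data
    generators for field trials and salt-affected regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
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
    fitdistrplus,
    knitr,
    nlme,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
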