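Package: causediv
Title: Diversity of Mortality Causes and Age-Standardised Mortality Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying trends in the diversity of causes of death
    across subpopulations from vital-registration style data. Builds
    population-weighted area-deprivation quintiles, directly age-standardised
    mortality rates against the 2013 European Standard Population,
    single-year-of-age period life tables with Kannisto-Makeham logistic
    extrapolation of old-age mortality, and multiple-decrement life tables
    whose cause-specific decrements feed Hill-number (effective number of
    causes) diversity measures and descriptive linear trend fits. Includes a
    seeded synthetic registry generator so the full pipeline is reproducible
    without access to confidential registry microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
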