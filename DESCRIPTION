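Package: lifehale
Title: Life Tables and Healthy Life Expectancy for Subpopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds smoothed complete period life tables from age-specific
    exposure and death schedules, extends old-age mortality with a registry of
    nine parametric hazard families, imputes sparse subgroup death rates through
    a logit-scale relational link to a standard population, abridges tables to
    five-year age groups, and computes healthy life expectancy by the Sullivan
    method under multiple unhealthy-prevalence definitions. Confidence
    intervals for life expectancy and healthy life expectancy follow Chiang's
    variance estimator. A synthetic-registry generator with a known
    Gompertz-Makeham ground truth supports end-to-end recovery testing when the
    underlying registry and claims data are restricted.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
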