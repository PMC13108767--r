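Package: pifcast
Title: Policy Scenario Modelling of Tobacco-Attributable Cancer Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the cancer burden preventable by tobacco
    control policies from country-level panel data. Fits two-way fixed-effects
    regressions of smoking prevalence on policy exposures (MPOWER score,
    cigarette affordability, adult literacy), builds counterfactual prevalence
    scenarios, interpolates five-year cancer incidence projections to annual
    series, computes Levin population attributable fractions and potential
    impact fractions, aggregates attributable and preventable case counts
    across countries, genders, cancer sites and development tiers, and
    quantifies uncertainty with a country-level nonparametric bootstrap.
    Includes a synthetic data generator with known ground truth for end-to-end
    validation.
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
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
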