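Package: cropdivr
Title: Crop Diversification and Pollinator-Dependence Trend Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long-term change in agricultural pollinator
    dependence and crop diversification from country-by-crop-by-year
    harvested-area panels in the FAOSTAT bulk dialect. Provides panel
    reading, validation, successor-state harmonization and minimum-area
    filtering; Klein-style pollinator-dependence classification and
    dependence shares; Shannon diversity, effective number of crops and
    Pielou evenness; compound annual growth rates, vulnerability indices,
    crop-expansion rankings, G-tests and correlations; heteroscedastic
    (per-region variance) generalized least squares with least-squares
    means and Tukey-adjusted contrasts; and a seeded synthetic-panel
    generator with closed-form ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    yaml
Suggests:
    MASS,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
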