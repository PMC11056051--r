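Package: equipanel
Title: Equity Analysis of Health-Resource Allocation over County-Year Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decadal health-resource equity analysis over balanced
    county-by-year panels: per-1000 bed, doctor and nurse densities, decade
    growth rates, staffing ratios, population-weighted Theil index with exact
    intra-/inter-category decomposition, and bivariate regressions of resource
    densities on income, GDP per capita and altitude. Includes a synthetic
    panel generator with known ground truth (category baselines, growth
    multipliers, covariate effects, multiplicative noise) so every pipeline
    stage is testable without the source yearbook, plus a config-driven
    end-to-end report runner and a comparator against published values.
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
    lmtest,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
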