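Package: eggdiapause
Title: Egg Diapause Phenology and Critical Photoperiod from Ovitrap Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analyse per-egg hatching and embryonation records from ovitrap
    surveillance of container-breeding mosquitoes (Aedes japonicus and
    relatives). Computes weekly hatching success, viability, mortality and
    diapause incidence; detects the sustained 50% seasonal diapause cut-off
    and converts it to a maternal critical photoperiod via astronomical
    day-length calculations; quantifies egg-morphometric seasonality
    (spheroid volume, weekly-median regressions, rank-based group contrasts);
    fits a logistic diapause-probability model with AIC-based predictor
    selection; and generates seeded synthetic ovitrap seasons so every stage
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    ggplot2
Config/testthat/edition: 3
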