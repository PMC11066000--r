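Package: robscore
Title: ROB Composite Severity Scoring and Survival Analysis for the
    Circle-of-Willis-Perforation SAH Mouse Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the ROB (Rotarod, Open-field, Body-weight-loss)
    composite severity-scoring protocol for the endovascular-perforation
    mouse model of subarachnoid hemorrhage. Maps raw behavioral
    measurements (Rotarod latency to fall, key-frame open-field path
    distance from tracked ear coordinates, daily body-weight loss) to 1-5
    sub-scores, a 3-15 total, and a severe/moderate/mild class; builds
    valid and scored cohorts under the protocol's exclusion rules;
    computes cumulative mortality with scheduled-autopsy denominator
    adjustment, Kaplan-Meier curves and log-rank subgroup comparisons
    with humane-endpoint deaths as events and scheduled euthanasia as
    censoring; detects longitudinal score decline; grades autopsies on
    six basal-cistern segments and measures concordance with the
    behavioral classification; and simulates complete synthetic cohorts
    so the whole pipeline is testable without animal data.
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
    survival,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
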