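Package: trawlshift
Title: Species Range-Shift Estimation from Bottom-Trawl Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates latitudinal range-shift rates of marine fish from
    bottom-trawl survey data. Computes annual biomass-weighted distribution
    centroids per species, models centroid latitude with a survey-footprint
    corrected generalized additive model to obtain shift rates in km/yr,
    tests community-level shifts (Shapiro-Wilk gated t-test or Wilcoxon with
    Hodges-Lehmann pseudomedian), fits two-part (hurdle) GAM thermal-envelope
    models with Duan smearing retransformation, projects thermal envelopes
    onto annual environmental grids to estimate envelope shift rates, and
    relates observed shifts to envelope shifts (Pearson tracking correlation,
    direction correspondence) and to species traits (generalized least
    squares with power variance). Includes a synthetic trawl-survey generator
    with closed-form ground-truth shift rates for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    nlme,
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
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
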