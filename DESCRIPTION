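Package: braincost
Title: Bottom-Up Cost-of-Illness Estimation for Brain Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A prevalence-based, bottom-up cost-of-illness pipeline for mental and
    neurological disorders, built around study-level per-patient cost observations.
    Observations reported in different currencies and costing years are harmonized
    to a common price level (EUR at 2010 prices by default) with nominal exchange
    rates and an all-items consumer price index, pooled by un-weighted means per
    disorder and cost category (direct healthcare, direct non-medical, indirect),
    completed by European median imputation where national evidence is missing,
    and scaled to societal costs via prevalence-based patient counts. Uncertainty
    is quantified by a quality-restricted re-analysis and a seeded Monte Carlo
    simulation with triangular distributions. A synthetic-corpus generator with
    analytically known ground truth supports end-to-end validation.
License: MIT
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
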