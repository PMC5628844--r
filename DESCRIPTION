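Package: opptrend
Title: Century-Scale Occurrence Trends from Opportunistic Specimen Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates long-term occurrence trends of species from
    opportunistic museum and private-collection records. Records are
    aggregated into collector day-lists, recorder effort is controlled with
    list-length and record-count covariates, and per-species reporting rates
    are modeled with Bernoulli logit generalized linear mixed models with
    county random intercepts, fit by maximum marginal likelihood using
    adaptive Gauss-Hermite quadrature. Candidate models differing in year and
    bioclimatic terms are ranked by AICc, combined by conditional model
    averaging, and species are classified as declining, increasing, or
    trendless from the averaged year coefficient's confidence interval.
    Includes derivation of bioclimatic covariates (Bio6, Bio10, Bio18) from
    monthly county series, two-tailed Fisher exact tests for trait-trend
    associations, and a synthetic-record generator with known ground truth
    for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
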