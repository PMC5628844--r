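---
title: "Effort-corrected occurrence trends from opportunistic records: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort-corrected occurrence trends from opportunistic records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model the package implements, the
choices made where the methodology left room for judgment, and what the
synthetic-data calibration studies do and do not demonstrate.

## The observation model

Opportunistic collection records carry no sampling design. The unit of
analysis is therefore the *list*: the set of species taken by one collector
at one locality on one date, interpreted as one finite sampling event. For
a focal species the response is its reporting rate — presence or absence on
each list — and detection probability is modeled on the logit scale as a
linear function of

* `year`, the trend term of interest;
* `log(L)` (natural log), where `L` is list length — the number of species
  on the list — the primary effort proxy: longer lists indicate more
  thorough recording, raising the chance that a present species was
  actually taken;
* `records`, the total number of individuals in the event, a second,
  complementary effort proxy;
* `bio6`, `bio10`, `bio18`: county-year bioclimatic covariates (minimum
  temperature of the coldest month in °C, relevant to overwinter larval
  survival; mean temperature in °C and precipitation in mm of the warmest
  quarter, relevant to adults);
* a county random intercept with mean zero and estimated variance,
  absorbing unmodeled spatial structure in both moth occurrence and
  collecting behavior.

All continuous predictors are standardized (mean subtracted, divided by the
standard deviation with the *n* − 1 denominator), once per activity-class
dataset so every species fitted from one dataset shares a scale. The
standardization constants are stored, and `coef_natural()` maps
coefficients and their covariance back to natural units exactly — the
intercept picks up `-sum(beta_j * m_j / s_j)`, each slope is divided by its
`s_j`.

Two inclusion rules precede fitting: lists with fewer than two species are
discarded as likely incomplete samples, and only species recorded on at
least ten lists are modeled (rarer species are reported as excluded). Both
thresholds are configurable.

## Likelihood and numerics

The county intercept is integrated out of the likelihood, which factorizes
over counties into one-dimensional integrals. Each integral is evaluated by
adaptive Gauss–Hermite quadrature: the integrand is re-centred at its
conditional mode (found by damped Newton iteration, step clamp ±3,
tolerance 1e-11) and rescaled by the curvature there, then evaluated on a
Gauss–Hermite grid (default 15 nodes; 1 node is exactly the Laplace
approximation). Log-sum-exp arithmetic is used throughout; the kernel is
compiled C++. Against 201-node non-adaptive brute-force quadrature the
15-node rule agrees to better than 1e-8 on datasets of the size fitted
here.

Maximization runs over the fixed coefficients and `log(sigma)` (the
variance parameter is unconstrained on the log scale), using L-BFGS-B with
the analytic quadrature gradient — the posterior expectation of the
complete-data score under the same rule — followed by Newton polishing
steps with a finite-difference Hessian, which drive the score max-norm
below 1e-6 (typically to ~1e-10). Standard errors come from the inverse of
the negative Hessian of the marginal log-likelihood at the optimum.

Degenerate cases are handled explicitly:

* `sigma = 0` reduces analytically to ordinary logistic regression; the
  same optimizer on the Bernoulli likelihood reproduces an independently
  coded IRLS solution to 1e-6 or better (tested).
* When the estimate of `sigma` collapses toward zero, the `log(sigma)`
  direction of the Hessian becomes numerically flat; standard errors then
  fall back to the fixed-effect block with `sigma` profiled at its
  estimate, and `sigma` below 1e-6 is reported as 0.
* Non-convergence (score norm above tolerance after 500 iterations) flags
  the fit; flagged fits are dropped from candidate sets with a warning,
  never silently patched.

## Multi-model inference

Every candidate model contains the intercept, both effort terms and the
county intercept; the 16 candidates toggle `year`, `bio6`, `bio10`,
`bio18`. Ranking uses AICc with `k` counting the fixed effects, the
intercept and the random-effect variance, and `n` equal to the number of
rows in the fitted response vector (the number of lists in the dataset) —
the natural choice since each list contributes one Bernoulli observation;
`k` and `n` are recorded per fit so sensitivity to this convention can be
checked. Exact AICc ties are ordered by the lexicographic model label.

Akaike weights are computed after subtracting the minimum AICc, so extreme
deltas underflow to zero weight rather than overflow. If one model carries
weight at least 0.9 it is retained alone; otherwise the best-model set
keeps every model whose weight is at least 5% of the best (evidence ratio
0.05). Coefficients are averaged *conditionally* — only over retained
models containing the term, with weights renormalized over those models.
The model-averaged standard error uses the revised unconditional estimator

```
SE_t = sum_i w_i * sqrt(SE_it^2 + (b_it - b_t_bar)^2)
```

the standard companion to conditional averaging; the methodology names
averaged standard errors without fixing a formula, so the choice is pinned
here and exercised by an exact worked example in the tests.

Trend calls use the averaged year coefficient with a normal 95% interval
(multiplier 1.96, configurable): *decline* if the interval lies below zero,
*increase* if above, *no trend* if it straddles zero. If no retained model
contains `year` there is no conditional average to classify; the species is
reported as *insufficient* rather than silently forced into a category.
The same interval rule is applied to climate terms when reporting them.

Collinearity diagnostics (VIF from regressing each standardized predictor
on the others, pairwise Spearman rank correlations) are computed for every
design and attached to the inference object; the default flag threshold is
VIF ≥ 5, a common rule of thumb — well above the values these designs
produce.

## Bioclimatic covariates

`bio6` is the minimum of the twelve monthly minimum temperatures. The
warmest quarter is the consecutive three-month window (within one calendar
year, no December–February wrap) maximizing the mean of monthly mean
temperature, ties broken toward the earliest start month and logged;
`bio10` is that window's mean temperature and `bio18` its precipitation
total. The calendar-window convention is a declared decision: for a
northern-hemisphere summer quantity the warmest window never straddles the
year boundary, and record years are calendar years. Temperature shifts move
`bio6`/`bio10` by exactly the shift and never change the window choice or
`bio18` (property-tested). The module consumes pre-aggregated monthly
county series; aggregation from gridded products is out of scope.

## What the generator emulates — and what it does not

`simulate_records()` inverts the observation model under conditions chosen
to mirror the motivating collection data:

* 1900–2012 span; sampling events placed by county-year Poisson draws whose
  yearly rate steps from 8 to 35 events/year at 1965, reproducing the
  marked and sustained mid-1960s increase in collecting; rates are split
  across counties by gamma(4, 4) multipliers, since opportunistic
  collecting clusters spatially.
* Target list lengths `1 + Poisson(lambda)` with `lambda` stepping from
  0.5 to 1.4 in 1978, giving mean lengths near 1.5 early and 2.4 late —
  the short-list regime of historical collections, with the late-1970s
  rise. Total records per event add `Poisson(1)` individuals beyond one
  per species, keeping the records-to-lists ratio near 2.5–3.
* Monthly climate: sinusoidal seasonal cycle (January trough, July peak),
  county offsets, independent monthly noise, and a small warming trend
  (0.008 °C/year) so climate terms are neither degenerate nor dominant.
* Detection of each focal species follows the logit model exactly, using
  the drawn effort covariates (standardized over events) and realized
  county intercepts drawn with SD 0.5.

List length is both a covariate and, in real data, an outcome of
detection. The generator resolves this circularity by treating the modeled
roster as a subset of a larger collected fauna: after focal detections are
drawn, each event is padded with background ("filler") taxa until the
realized list reaches its drawn target length. List building then recovers
the generative covariates exactly, except in the minority of events where
focal detections overflow the target (realized `L` then exceeds the drawn
covariate — honest noise of the same kind real collecting produces). This
differs from data in which the recorded fauna *is* the focal taxon and
`L` counts focal species only; in that regime the circularity is intrinsic
and coefficient recovery is necessarily approximate.

Deliberately not emulated: within-season phenology (months are uniform over
May–September regardless of a species' flight period trait), spatially
explicit geography, migration, collector-specific behavior, taxonomic
uncertainty. Passing calibration tests therefore demonstrates that the
estimation machinery is correct *given the model*, not that the model is
adequate for any particular real dataset.

## Calibration studies and problem sizes

The acceptance tests simulate 100 replicates per scenario of a
single-species dataset with about 2000 sampling events in 15 counties
(county SD 0.5), the full seven-term model refit through list building.
Coverage of 95% intervals is checked per coefficient on the natural scale
— where generator and analysis standardizations coincide exactly, since the
analysis standardizes after the short-list filter and the generator before.
Under a standardized year effect of −0.5 the decline-call rate is required
to reach 95%; under a null year effect combined false calls must stay
within 10%. Observed values sit near 95–98% coverage, 100% decline calls,
and 2–5% false calls. `scripts/acceptance.R` reruns a 40-replicate version
of the same study from a user seed. These sizes were chosen to estimate
binomial rates to a few percent while keeping a full run in minutes on one
CPU.

## Known limitations

* One grouping factor only: no crossed collector effects, no
  spatio-temporal autocorrelation beyond the county intercept, no
  overdispersion term.
* Conditional model averaging shares the general caveats of averaging
  regression coefficients across models; the full-model fit is always
  available as a check.
* The AICc `n` convention (rows of the response vector) is a choice;
  alternatives (e.g. effective number of events) can be explored through
  the recorded `k` and `n`.
* County matching is exact string equality after case-folding and
  trimming; no fuzzy locality or collector deduplication is attempted.
* The Fisher test module handles 2×2 tables only, by design.
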