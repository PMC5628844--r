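test_that("candidate enumeration covers all subsets over the effort-only base", {
  specs <- enumerate_models()
  expect_length(specs, 16)
  labels <- vapply(specs, `[[`, "", "label")
  expect_false(any(duplicated(labels)))
  # every candidate retains the recorder-bias controls
  expect_true(all(vapply(specs, function(s)
    all(c("logL", "records") %in% s$terms), logical(1))))
  # effort-only null present
  expect_true("logL+records" %in% labels)
  expect_length(enumerate_models(character()), 1)
  expect_length(enumerate_models(c("year", "bio6")), 4)
  expect_error(model_spec("bogus"), "unknown")
})

test_that("Akaike weights follow the exp(-delta/2) form and are stable", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(akaike_weights(rep(7, 5)), rep(0.2, 5))
  w2 <- akaike_weights(c(0, 200))
  expect_equal(sum(w2), 1, tolerance = 1e-15)
  expect_gte(w2[1], 1 - 1e-20)
})

test_that("the evidence-ratio rule and dominance rule pick the right sets", {
  expect_equal(best_model_set(c(0.6, 0.3, 0.02)), c(TRUE, TRUE, FALSE))
  # one overwhelming model is retained alone
  expect_equal(best_model_set(c(0.95, 0.04, 0.01)), c(TRUE, FALSE, FALSE))
  expect_true(all(best_model_set(rep(0.25, 4))))
  # just below dominance: evidence-ratio rule applies
  expect_equal(best_model_set(c(0.89, 0.1, 0.01)), c(TRUE, TRUE, FALSE))
})

test_that("conditional averaging renormalizes over containing models", {
  est <- cbind(x = c(0.5, 0.3, NA))
  se <- cbind(x = c(0.1, 0.2, NA))
  avg <- model_average(est, se, c(0.6, 0.2, 0.2))
  expect_equal(avg$estimate, 0.45, tolerance = 1e-12)
  expect_equal(avg$n_models, 2)
  expect_equal(avg$weight_sum, 0.8)
  # term in a single model: that model's estimate and SE pass through
  one <- model_average(cbind(z = c(NA, 0.7)), cbind(z = c(NA, 0.25)),
                       c(0.9, 0.1))
  expect_equal(one$estimate, 0.7)
  expect_equal(one$se, 0.25)
  # identical estimates across models average to themselves
  same <- model_average(cbind(q = c(0.4, 0.4, 0.4)),
                        cbind(q = c(0.1, 0.2, 0.3)), c(0.5, 0.3, 0.2))
  expect_equal(same$estimate, 0.4)
  # averaged SE combines within-model and between-model spread
  spread <- model_average(cbind(x = c(1, -1)), cbind(x = c(0, 0)),
                          c(0.5, 0.5))
  expect_equal(spread$estimate, 0)
  expect_equal(spread$se, 1)  # pure between-model component
})

test_that("trend calls implement the CI-versus-zero rule", {
  expect_equal(classify_trend(-0.5, 0.1)$call, "decline")
  expect_equal(classify_trend(-0.5, 0.1)$ci_low, -0.696)
  expect_equal(classify_trend(0.1, 0.2)$call, "no_trend")
  expect_equal(classify_trend(0.4, 0.1)$call, "increase")
  expect_equal(classify_trend(NA_real_, NA_real_)$call, "insufficient")
  # boundary: interval touching zero is not a trend
  expect_equal(classify_trend(-0.196, 0.1)$call, "no_trend")
})

test_that("collinearity diagnostics flag redundancy and rank correlation", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)
  rep1 <- collinearity_report(cbind(a = x1, b = x2))
  expect_equal(unname(rep1$vif), c(1, 1), tolerance = 1e-10)
  expect_length(rep1$flagged, 0)
  set.seed(2)
  z <- rnorm(n)
  rep2 <- collinearity_report(cbind(a = z, b = z, c = rnorm(n)))
  expect_true(all(is.infinite(rep2$vif[c("a", "b")])))
  expect_true(all(c("a", "b") %in% rep2$flagged))
  # strictly monotone transform has Spearman rho 1
  rep3 <- collinearity_report(cbind(a = z, b = exp(z)))
  expect_equal(rep3$spearman["a", "b"], 1)
})

test_that("per-species inference composes ranking, averaging and calls", {
  cfg <- simulation_config(
    seed = 99, n_species = 2, n_counties = 6,
    true_coefficients = rbind(c(-0.8, -1.2, 1, 0.3, 0, 0, 0),
                              c(-0.8, 0, 1, 0.3, 0, 0, 0)),
    year_range = c(1950, 2012),
    effort_regime = list(breakpoint = 1965, events_per_year_before = 6,
                         events_per_year_after = 10))
  sim <- simulate_records(cfg)
  ev <- suppressMessages(filter_events(build_lists(sim$records), 2))
  ds <- suppressMessages(as_analysis_dataset(
    ev, min_lists = 10, species = c("species_01", "species_02")))
  covs <- suppressMessages(county_year_covariates(sim$climate))
  inf <- suppressMessages(suppressWarnings(
    run_species_inference(ds, covs, nodes = 5)))

  for (sp in unique(inf$candidates$species)) {
    cand <- inf$candidates[inf$candidates$species == sp, ]
    expect_equal(sum(cand$weight), 1, tolerance = 1e-12)
    expect_equal(cand$delta[which.min(cand$aicc)], 0)
    expect_equal(nrow(cand), 16)
  }
  # a strong simulated decline is called, a null species is not
  tr <- inf$trends
  expect_equal(tr$call[tr$species == "species_01"], "decline")
  expect_true(tr$call[tr$species == "species_02"] %in%
                c("no_trend", "insufficient"))
  # averaged coefficients exist for every retained term
  expect_true(all(c("logL", "records") %in%
                    inf$averaged$term[inf$averaged$species == "species_01"]))
})
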