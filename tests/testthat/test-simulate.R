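small_cfg <- function(...) {
  simulation_config(
    n_counties = 4, n_species = 3, year_range = c(1950, 1990),
    effort_regime = list(breakpoint = 1965, events_per_year_before = 4,
                         events_per_year_after = 12),
    ...)
}

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(year_range = c(2000, 2000)))
  expect_error(simulation_config(county_sd = -1))
  expect_error(simulation_config(effort_regime = list(
    breakpoint = 1965, events_per_year_before = 0,
    events_per_year_after = 10)))
  expect_error(simulation_config(n_species = 2,
                                 true_coefficients = matrix(0, 3, 7)))
})

test_that("climate simulation is reproducible and has the right shape", {
  cfg <- simulation_config(n_counties = 2, year_range = c(2000, 2002),
                           seed = 5)
  cl1 <- simulate_climate(cfg)
  cl2 <- simulate_climate(cfg)
  expect_identical(cl1, cl2)
  expect_equal(nrow(cl1), 2 * 3 * 12)
  expect_equal(sort(unique(cl1$month)), 1:12)
  expect_true(all(cl1$prcp_mm >= 0))
  # July is the warm pole of the seasonal cycle
  jul <- mean(cl1$tmean_C[cl1$month == 7])
  jan <- mean(cl1$tmean_C[cl1$month == 1])
  expect_gt(jul, jan + 15)
})

test_that("zero noise and identical counties collapse to one shared series", {
  cfg <- simulation_config(
    n_counties = 3, year_range = c(2000, 2001), seed = 2,
    climate = list(tmean_jan = -5, tmean_jul = 22, tmin_offset = 6,
                   prcp_monthly_mean = 100, prcp_summer_excess = 20,
                   county_sd_T = 0, county_sd_P = 0, noise_T = 0,
                   noise_P = 0, warming_per_year = 0))
  cl <- simulate_climate(cfg)
  by_county <- split(cl[, c("tmin_C", "tmean_C", "prcp_mm")], cl$county)
  for (i in 2:3)
    expect_equal(by_county[[i]], by_county[[1]], ignore_attr = TRUE)
})

test_that("record simulation is deterministic under the master seed", {
  cfg <- small_cfg(seed = 77)
  s1 <- simulate_records(cfg)
  s2 <- simulate_records(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$probabilities, s2$truth$probabilities)
  # climate embedded in the records run equals the standalone draw
  expect_identical(s1$climate, simulate_climate(cfg))
})

test_that("an impossible species never appears; effort steps up at the breakpoint", {
  tc <- rbind(c(-1, 0, 1, 0.3, 0, 0, 0),
              c(-Inf, 0, 1, 0.3, 0, 0, 0),
              c(-1, 0, 1, 0.3, 0, 0, 0))
  sim <- simulate_records(small_cfg(seed = 8, true_coefficients = tc))
  expect_false("species_02" %in% sim$records$species)
  expect_true("species_01" %in% sim$records$species)
  evyr <- table(factor(sim$truth$event_covariates$year, levels = 1950:1990))
  expect_gt(mean(evyr[as.integer(names(evyr)) >= 1965]),
            mean(evyr[as.integer(names(evyr)) < 1965]))
  # ground-truth probabilities for possible species stay inside (0, 1)
  expect_true(all(sim$truth$probabilities[, c(1, 3)] > 0 &
                    sim$truth$probabilities[, c(1, 3)] < 1))
  expect_true(all(sim$truth$probabilities[, 2] == 0))
})

test_that("realized detections follow the logistic curve in the linear predictor", {
  tc <- matrix(c(-1, 0, 1, 0.3, 0, 0, 0), 1)
  cfg <- simulation_config(
    n_counties = 5, n_species = 1, year_range = c(1950, 2012), seed = 12,
    true_coefficients = tc, county_sd = 0.4,
    effort_regime = list(breakpoint = 1965, events_per_year_before = 30,
                         events_per_year_after = 60))
  sim <- simulate_records(cfg)
  p <- sim$truth$probabilities[, 1]
  y <- sim$truth$detections[, 1]
  bins <- cut(qlogis(p), quantile(qlogis(p), 0:5 / 5), include.lowest = TRUE)
  obs <- tapply(y, bins, mean)
  expt <- tapply(p, bins, mean)
  nbin <- tapply(y, bins, length)
  z <- (obs - expt) / sqrt(expt * (1 - expt) / nbin)
  expect_true(all(abs(z) < 4))  # within binomial error per bin

  # yearly event counts reproduce the effort regime within Poisson error
  n_pre <- sum(sim$truth$event_covariates$year < 1965)
  expect_lt(abs(n_pre - 15 * 30) / sqrt(15 * 30), 4)
})

test_that("list building recovers the generative effort covariates", {
  sim <- simulate_records(small_cfg(seed = 31))
  ev <- suppressMessages(build_lists(sim$records))
  tr <- sim$truth$event_covariates
  key_t <- paste(tr$locality,
                 sprintf("%04d-%02d-%02d", tr$year, tr$month, tr$day),
                 tr$collector)
  key_e <- paste(ev$events$locality, ev$events$date, ev$events$collector)
  idx <- match(key_e, key_t)
  expect_false(anyNA(idx))
  expect_equal(nrow(ev$events), nrow(tr))
  # records always match; L matches except when detections overflowed the
  # target list length (rare, logged as a property of the design)
  expect_true(all(ev$events$records >= tr$records[idx]))
  expect_gt(mean(ev$events$L == tr$L[idx]), 0.75)
  expect_true(all(ev$events$L >= tr$L[idx]))
})

test_that("trait tables cover every simulated species", {
  sim <- simulate_records(small_cfg(seed = 4))
  expect_true(all(unique(sim$records$species) %in% sim$traits$species))
  expect_setequal(unique(sim$traits$activity), c("diurnal", "nocturnal"))
  expect_equal(sum(sim$traits$focal), 3)
})

test_that("YAML simulation configs round-trip", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_counties = 3, n_species = 2,
                        year_range = c(1960, 1980), seed = 9,
                        county_sd = 0.3,
                        effort_regime = list(events_per_year_before = 5)),
                   path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "opp_sim_config")
  expect_equal(cfg$n_counties, 3)
  expect_equal(cfg$year_range, c(1960, 1980))
  expect_equal(cfg$effort_regime$events_per_year_before, 5)
  expect_equal(cfg$effort_regime$breakpoint, 1965)  # default preserved
  expect_equal(nrow(cfg$true_coefficients), 2)
})
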