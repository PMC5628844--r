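#' Configuration for the synthetic record generator
#'
#' Defines the study conditions the generator emulates: a 1900--2012 span of
#' opportunistic collecting across counties, sampling effort that jumps
#' sharply in the mid-1960s, short species lists whose mean length rises in
#' the late 1970s, and per-species detection following the random-intercept
#' logistic observation model with known coefficients on the standardized
#' scale.
#'
#' @param n_counties number of counties (random-intercept groups).
#' @param year_range inclusive first and last year.
#' @param n_species number of modeled (focal) species.
#' @param true_coefficients `n_species x 7` matrix of per-species
#'   coefficients on the standardized-predictor scale, columns
#'   `(intercept)`, `year`, `logL`, `records`, `bio6`, `bio10`, `bio18`;
#'   `NULL` for a default roster mixing declining, stable and increasing
#'   species.
#' @param county_sd SD of the county random intercepts.
#' @param effort_regime list: `breakpoint` year, `events_per_year_before`,
#'   `events_per_year_after` (expected sampling events per year, totalled
#'   over counties).
#' @param list_size list `lambda_before`, `lambda_after`, `changepoint`:
#'   the target list length of an event is `1 + Poisson(lambda)`, with the
#'   rate stepping up at the changepoint year.
#' @param records_extra_lambda expected individuals beyond one per listed
#'   species (total records per event = L + Poisson(this)).
#' @param climate list of climate-process constants: January and July mean
#'   temperatures (`tmean_jan`, `tmean_jul`, degrees C), `tmin_offset`
#'   (degrees below the monthly mean for the monthly minimum),
#'   `prcp_monthly_mean` and `prcp_summer_excess` (mm), county spreads
#'   `county_sd_T`/`county_sd_P`, noise SDs `noise_T`/`noise_P`, and a
#'   linear `warming_per_year` trend.
#' @param diurnal_fraction,tree_vine_fraction,spring_fraction,pest_fraction
#'   trait-assignment probabilities for the focal species.
#' @param n_filler_species,filler_nocturnal_fraction background community:
#'   non-focal taxa used to pad lists to their target length.
#' @param n_sites_per_county,n_collectors label pools for localities and
#'   collector names.
#' @param seed master seed; all draws flow from one generator.
#' @return validated list of class `opp_sim_config`.
#' @export
simulation_config <- function(n_counties = 15,
                              year_range = c(1900, 2012),
                              n_species = 10,
                              true_coefficients = NULL,
                              county_sd = 0.5,
                              effort_regime = list(
                                breakpoint = 1965,
                                events_per_year_before = 8,
                                events_per_year_after = 35),
                              list_size = list(
                                lambda_before = 0.5,
                                lambda_after = 1.4,
                                changepoint = 1978),
                              records_extra_lambda = 1,
                              climate = list(
                                tmean_jan = -5, tmean_jul = 22,
                                tmin_offset = 6,
                                prcp_monthly_mean = 100,
                                prcp_summer_excess = 20,
                                county_sd_T = 1.2, county_sd_P = 15,
                                noise_T = 1.5, noise_P = 25,
                                warming_per_year = 0.008),
                              diurnal_fraction = 0.2,
                              tree_vine_fraction = 0.5,
                              spring_fraction = 0.2,
                              pest_fraction = 0.1,
                              n_filler_species = 60,
                              filler_nocturnal_fraction = 0.85,
                              n_sites_per_county = 40,
                              n_collectors = 30,
                              seed = 1) {
  if (is.null(true_coefficients))
    true_coefficients <- default_true_coefficients(n_species)
  true_coefficients <- as.matrix(true_coefficients)
  colnames(true_coefficients) <- COEF_NAMES
  cfg <- structure(as.list(environment()), class = "opp_sim_config")
  validate_sim_config(cfg)
  cfg
}

COEF_NAMES <- c("(intercept)", "year", "logL", "records",
                "bio6", "bio10", "bio18")

default_true_coefficients <- function(n_species) {
  cyc <- function(v) rep_len(v, n_species)
  cbind("(intercept)" = seq(-2.8, -1.4, length.out = n_species),
        year = cyc(c(-0.8, -0.4, 0, 0, 0.4)),
        logL = 1.0, records = 0.3,
        bio6 = cyc(c(0.3, 0, 0, -0.2, 0)),
        bio10 = cyc(c(0, -0.3, 0, 0.2, 0)),
        bio18 = cyc(c(0, 0, 0.2, 0, 0)))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_counties >= 1, cfg$n_species >= 1,
            length(cfg$year_range) == 2,
            cfg$year_range[2] > cfg$year_range[1],
            cfg$county_sd >= 0,
            cfg$effort_regime$events_per_year_before > 0,
            cfg$effort_regime$events_per_year_after > 0,
            cfg$list_size$lambda_before >= 0,
            cfg$list_size$lambda_after >= 0,
            cfg$records_extra_lambda >= 0,
            nrow(cfg$true_coefficients) == cfg$n_species,
            ncol(cfg$true_coefficients) == 7)
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields and the nested `effort_regime`/`list_size`/`climate` blocks
#' map one-to-one onto [simulation_config()] arguments; `true_coefficients`
#' may be given as a list of 7-element rows.
#'
#' @param path YAML file.
#' @return an `opp_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$true_coefficients))
    raw$true_coefficients <- do.call(rbind, raw$true_coefficients)
  if (!is.null(raw$year_range)) raw$year_range <- as.numeric(raw$year_range)
  defaults <- formals(simulation_config)
  for (blk in c("effort_regime", "list_size", "climate"))
    if (!is.null(raw[[blk]]))
      raw[[blk]] <- modifyList(eval(defaults[[blk]]), raw[[blk]])
  do.call(simulation_config, raw[names(raw) %in% names(defaults)])
}

## Climate draws shared by simulate_climate() and simulate_records(); must
## be called directly after set.seed(cfg$seed) so both entry points see
## identical series.
simulate_climate_core <- function(cfg) {
  cl <- cfg$climate
  counties <- sprintf("county_%02d", seq_len(cfg$n_counties))
  years <- cfg$year_range[1]:cfg$year_range[2]
  dT <- rnorm(cfg$n_counties, 0, cl$county_sd_T)
  dP <- rnorm(cfg$n_counties, 0, cl$county_sd_P)
  g <- expand.grid(month = 1:12, year = years, county = counties,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ci <- match(g$county, counties)
  base <- (cl$tmean_jan + cl$tmean_jul) / 2
  amp <- (cl$tmean_jul - cl$tmean_jan) / 2
  season <- cos(2 * pi * (g$month - 7) / 12)
  trend <- cl$warming_per_year * (g$year - cfg$year_range[1])
  tmean <- base + amp * season + trend + dT[ci] +
    rnorm(nrow(g), 0, cl$noise_T)
  tmin <- tmean - cl$tmin_offset + rnorm(nrow(g), 0, cl$noise_T / 2)
  prcp <- pmax(0, cl$prcp_monthly_mean + cl$prcp_summer_excess * season +
                 dP[ci] + rnorm(nrow(g), 0, cl$noise_P))
  data.frame(county = g$county, year = g$year, month = g$month,
             tmin_C = round(tmin, 2), tmean_C = round(tmean, 2),
             prcp_mm = round(prcp, 1))
}

#' Simulate monthly county climate series
#'
#' A sinusoidal seasonal cycle (January minimum, July maximum) plus a linear
#' warming trend, a county offset, and independent monthly noise, for the
#' three series the bioclimatic derivation consumes.  Reproducible under the
#' configuration seed.
#'
#' @param cfg an `opp_sim_config`.
#' @return data.frame `county`, `year`, `month`, `tmin_C`, `tmean_C`,
#'   `prcp_mm` (12 rows per county-year).
#' @export
simulate_climate <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  simulate_climate_core(cfg)
}

simulate_traits_core <- function(cfg) {
  focal <- sprintf("species_%02d", seq_len(cfg$n_species))
  filler <- sprintf("background_sp_%02d", seq_len(cfg$n_filler_species))
  n_all <- length(focal) + length(filler)
  act <- c(ifelse(runif(cfg$n_species) < cfg$diurnal_fraction,
                  "diurnal", "nocturnal"),
           ifelse(runif(cfg$n_filler_species) < cfg$filler_nocturnal_fraction,
                  "nocturnal", "diurnal"))
  data.frame(
    species = c(focal, filler),
    focal = c(rep(TRUE, cfg$n_species), rep(FALSE, cfg$n_filler_species)),
    activity = act,
    host_habit = ifelse(runif(n_all) < cfg$tree_vine_fraction,
                        "tree_vine", "shrub_herb"),
    flight_period = ifelse(runif(n_all) < cfg$spring_fraction,
                           "spring", "summer"),
    crop_pest = runif(n_all) < cfg$pest_fraction)
}

#' Simulate opportunistic specimen records with known ground truth
#'
#' Inverts the observation model: sampling events are placed in (county,
#' year) cells by a Poisson process whose yearly rate follows the two-level
#' effort regime, split across counties by gamma-distributed county
#' multipliers (opportunistic collecting clusters spatially).  Each event
#' draws a target list length `L` and total record count, which -- together
#' with the county-year bioclimatic values and the event's year, all
#' standardized over events -- form the covariates of the logistic model.
#' Each focal species is then recorded with its model probability given the
#' county's realized random intercept.  Events are finally padded with
#' background (non-focal) taxa so the realized list length equals the drawn
#' covariate: the modeled roster is a subset of a larger collected fauna,
#' as in real collections.
#'
#' @param cfg an `opp_sim_config`.
#' @return list of class `opp_simulation`:
#'   `records` (one row per individual: `species`, `year`, `month`, `day`,
#'   `locality`, `county`, `collector`), `traits` (focal and background
#'   species), `climate` (monthly series), and `truth` (class `opp_truth`:
#'   true coefficient matrix, realized county intercepts with their sample
#'   mean, per-(event, species) detection probabilities, the event
#'   covariates on raw and standardized scales, and the standardization
#'   constants).
#' @export
simulate_records <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  climate <- simulate_climate_core(cfg)
  covars <- county_year_covariates(climate)

  counties <- sprintf("county_%02d", seq_len(cfg$n_counties))
  years <- cfg$year_range[1]:cfg$year_range[2]
  b_county <- rnorm(cfg$n_counties, 0, cfg$county_sd)
  names(b_county) <- counties
  mult <- rgamma(cfg$n_counties, shape = 4, rate = 4)
  w <- mult / sum(mult)

  er <- cfg$effort_regime
  rate_year <- ifelse(years < er$breakpoint,
                      er$events_per_year_before, er$events_per_year_after)
  cell <- expand.grid(county = counties, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_ev <- rpois(nrow(cell), rate_year[match(cell$year, years)] *
                  w[match(cell$county, counties)])
  ev <- cell[rep(seq_len(nrow(cell)), n_ev), , drop = FALSE]
  n <- nrow(ev)
  if (n < 2) stop("effort regime produced fewer than two events")

  ls <- cfg$list_size
  lambda_L <- ifelse(ev$year < ls$changepoint,
                     ls$lambda_before, ls$lambda_after)
  ev$L <- 1L + rpois(n, lambda_L)
  ev$records <- ev$L + rpois(n, cfg$records_extra_lambda)
  ev$month <- sample(5:9, n, replace = TRUE)
  ev$day <- sample(1:28, n, replace = TRUE)
  site <- sample.int(cfg$n_sites_per_county, n, replace = TRUE)
  ev$locality <- sprintf("%s_site_%02d", ev$county, site)
  ev$collector <- sprintf("collector_%02d",
                          sample.int(cfg$n_collectors, n, replace = TRUE))
  ## (locality, date, collector) is the sampling-event key downstream;
  ## redraw days for the rare collisions so simulated events stay distinct.
  for (i in 1:50) {
    key <- paste(ev$locality, ev$year, ev$month, ev$day, ev$collector)
    dup <- duplicated(key)
    if (!any(dup)) break
    ev$day[dup] <- sample(1:28, sum(dup), replace = TRUE)
    ev$month[dup] <- sample(5:9, sum(dup), replace = TRUE)
  }
  if (any(duplicated(paste(ev$locality, ev$year, ev$month, ev$day,
                           ev$collector))))
    stop("could not make sampling-event keys unique; enlarge label pools")
  rownames(ev) <- NULL

  ev <- attach_covariates(ev, covars)
  raw <- cbind(year = ev$year, logL = log(ev$L), records = ev$records,
               bio6 = ev$bio6, bio10 = ev$bio10, bio18 = ev$bio18)
  std <- standardize_columns(raw)

  beta <- cfg$true_coefficients
  rownames(beta) <- sprintf("species_%02d", seq_len(cfg$n_species))
  eta <- cbind(1, std$x) %*% t(beta)  # events x species
  eta <- eta + b_county[match(ev$county, counties)]
  if (any(is.nan(eta)))
    stop("true detection probability is not finite; check coefficients")
  p <- plogis(eta)
  colnames(p) <- sprintf("species_%02d", seq_len(cfg$n_species))
  y <- matrix(rbinom(length(p), 1, p), nrow = n,
              dimnames = dimnames(p))

  traits <- simulate_traits_core(cfg)
  filler_pool <- traits$species[!traits$focal]

  sp_by_event <- vector("list", n)
  for (i in seq_len(n)) {
    det <- colnames(y)[y[i, ] == 1L]
    n_fill <- max(0L, ev$L[i] - length(det))
    fill <- if (n_fill) sample(filler_pool, min(n_fill, length(filler_pool)))
            else character()
    spp <- c(det, fill)
    n_real <- length(spp)
    total <- max(ev$records[i], n_real)
    extra <- drop(rmultinom(1, total - n_real, rep(1, n_real)))
    sp_by_event[[i]] <- rep(spp, 1L + extra)
  }
  per_event <- lengths(sp_by_event)
  eidx <- rep(seq_len(n), per_event)
  records <- data.frame(species = unlist(sp_by_event, use.names = FALSE),
                        year = ev$year[eidx],
                        month = ev$month[eidx],
                        day = ev$day[eidx],
                        locality = ev$locality[eidx],
                        county = ev$county[eidx],
                        collector = ev$collector[eidx])

  truth <- structure(list(
    coefficients = beta,
    county_intercepts = b_county,
    county_intercept_mean = mean(b_county),
    county_multipliers = setNames(mult, counties),
    probabilities = p,
    detections = y,
    event_covariates = cbind(
      ev[, c("county", "year", "month", "day", "locality", "collector",
             "L", "records", "bio6", "bio10", "bio18")],
      setNames(as.data.frame(std$x), paste0("z_", colnames(std$x)))),
    center = std$center, scale = std$scale,
    config = cfg
  ), class = "opp_truth")

  structure(list(records = records, traits = traits, climate = climate,
                 truth = truth),
            class = "opp_simulation")
}

#' @export
print.opp_simulation <- function(x, ...) {
  cat("Synthetic opportunistic-record dataset:",
      nrow(x$records), "records,",
      nrow(x$truth$event_covariates), "sampling events,",
      sum(x$traits$focal), "focal species,",
      x$truth$config$n_counties, "counties\n")
  invisible(x)
}

#' @export
print.opp_truth <- function(x, ...) {
  cat("Simulation ground truth:", nrow(x$coefficients),
      "species; county intercept SD", x$config$county_sd,
      "(realized mean", round(x$county_intercept_mean, 3), ")\n")
  invisible(x)
}
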