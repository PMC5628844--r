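#' Bioclimatic covariates from monthly county series
#'
#' Three of the standard bioclimatic variables drive the climate terms of the
#' occurrence model: Bio6, the minimum temperature of the coldest month
#' (overwinter larval survival); Bio10, the mean temperature of the warmest
#' quarter; and Bio18, the precipitation of the warmest quarter (both
#' relevant to adult survival).  Quarters are consecutive three-month windows
#' within one calendar year (no December--February wrap); ties between
#' windows are broken toward the earliest start month.
#'
#' @param monthly_tmin,monthly_tmean,monthly_prcp numeric vectors of exactly
#'   12 monthly values (January..December); temperatures in degrees Celsius,
#'   precipitation totals in millimeters.
#' @return `bio6()`: the minimum monthly minimum temperature (degrees C).
#'   `warmest_quarter()`: the start month (1..10) of the consecutive
#'   three-month window with the highest mean temperature.
#'   `bio10_bio18()`: list with `bio10` (degrees C), `bio18` (mm), and
#'   `quarter_start`.
#' @examples
#' bio6(c(-8, -10, -3, 2, 8, 13, 16, 15, 10, 4, -1, -6))
#' @name bioclim
NULL

check_12 <- function(x, what) {
  if (length(x) != 12)
    stop(what, ": expected 12 monthly values, got ", length(x))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(what, ": missing or non-finite value for month(s) ",
         paste(month.abb[bad], collapse = ", "))
  as.numeric(x)
}

#' @rdname bioclim
#' @export
bio6 <- function(monthly_tmin) {
  min(check_12(monthly_tmin, "monthly_tmin"))
}

#' @rdname bioclim
#' @export
warmest_quarter <- function(monthly_tmean) {
  x <- check_12(monthly_tmean, "monthly_tmean")
  means <- vapply(1:10, function(s) mean(x[s:(s + 2)]), numeric(1))
  best <- which(means == max(means))
  if (length(best) > 1)
    message("warmest-quarter tie between start months ",
            paste(month.abb[best], collapse = ", "), "; using earliest")
  best[1]
}

#' @rdname bioclim
#' @export
bio10_bio18 <- function(monthly_tmean, monthly_prcp) {
  tm <- check_12(monthly_tmean, "monthly_tmean")
  pr <- check_12(monthly_prcp, "monthly_prcp")
  s <- warmest_quarter(tm)
  win <- s:(s + 2)
  list(bio10 = mean(tm[win]), bio18 = sum(pr[win]), quarter_start = s)
}

#' Per county-year bioclimatic covariate table
#'
#' Reduces a monthly climate table to one row per (county, year) carrying
#' Bio6, Bio10 and Bio18, ready to join onto sampling events.
#'
#' @param climate data.frame with columns `county`, `year`, `month`,
#'   `tmin_C`, `tmean_C`, `prcp_mm`; every (county, year) must have all 12
#'   months exactly once.
#' @return data.frame with columns `county`, `year`, `bio6`, `bio10`,
#'   `bio18`, ordered by county then year.
#' @seealso [bioclim] for the per-series definitions,
#'   [attach_covariates()] for the join onto events.
#' @export
county_year_covariates <- function(climate) {
  need <- c("county", "year", "month", "tmin_C", "tmean_C", "prcp_mm")
  miss <- setdiff(need, names(climate))
  if (length(miss))
    stop("climate table lacks column(s): ", paste(miss, collapse = ", "))
  key <- interaction(climate$county, climate$year, drop = TRUE)
  out <- lapply(split(climate, key), function(d) {
    d <- d[order(d$month), ]
    if (!identical(as.integer(d$month), 1:12))
      stop("county ", d$county[1], ", year ", d$year[1],
           ": months are not exactly 1..12")
    q <- bio10_bio18(d$tmean_C, d$prcp_mm)
    data.frame(county = d$county[1], year = d$year[1],
               bio6 = bio6(d$tmin_C), bio10 = q$bio10, bio18 = q$bio18)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$county, out$year), ]
  rownames(out) <- NULL
  if (any(out$bio18 < 0)) stop("negative warmest-quarter precipitation")
  out
}

#' Attach county-year covariates to sampling events
#'
#' @param events data.frame with `county` and `year` columns (typically the
#'   `events` element of an [build_lists()] result).
#' @param covariates output of [county_year_covariates()].
#' @return `events` with `bio6`, `bio10`, `bio18` columns appended; errors
#'   listing every (county, year) present in `events` but absent from the
#'   covariate table.
#' @export
attach_covariates <- function(events, covariates) {
  key_e <- paste(norm_label(events$county), events$year, sep = "\r")
  key_c <- paste(norm_label(covariates$county), covariates$year, sep = "\r")
  idx <- match(key_e, key_c)
  if (anyNA(idx)) {
    off <- unique(paste0(events$county, ":", events$year)[is.na(idx)])
    stop("no climate covariates for (county, year): ",
         paste(off, collapse = ", "))
  }
  cbind(events, covariates[idx, c("bio6", "bio10", "bio18"), drop = FALSE],
        row.names = NULL)
}

## Counties are matched on case-folded, whitespace-trimmed labels.
norm_label <- function(x) tolower(trimws(as.character(x)))
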