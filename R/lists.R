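#' Merge species labels before list building
#'
#' Some taxa cannot be reliably told apart on specimens (sibling-species
#' complexes); their records are pooled under one label before any
#' aggregation.
#'
#' @param records record table (one row per individual).
#' @param merge_map named character vector, `old_label = new_label`.
#' @return the record table with `species` rewritten.
#' @examples
#' rec <- data.frame(species = c("a", "b"), year = 2000)
#' taxon_merge(rec, c(a = "ab", b = "ab"))$species
#' @export
taxon_merge <- function(records, merge_map) {
  if (is.null(merge_map) || !length(merge_map)) return(records)
  stopifnot(!is.null(names(merge_map)))
  hit <- records$species %in% names(merge_map)
  records$species[hit] <- unname(merge_map[records$species[hit]])
  records
}

record_date <- function(records) {
  ## Records lacking day/month precision key on the bare year, so museum
  ## labels with year-only dates form their own sampling events.
  m <- suppressWarnings(as.integer(records$month))
  d <- suppressWarnings(as.integer(records$day))
  ifelse(!is.na(m) & !is.na(d),
         sprintf("%04d-%02d-%02d", as.integer(records$year), m, d),
         sprintf("%04d", as.integer(records$year)))
}

#' Aggregate specimen records into sampling-event lists
#'
#' A "list" is the set of species taken by one collector at one locality on
#' one date -- the unit of sampling effort in opportunistic collections.
#' Each event carries its list length `L` (number of distinct species) and
#' `records` (total individuals across species), the two recorder-effort
#' proxies used as covariates downstream.
#'
#' Rows with missing species, locality, county, collector or year are
#' rejected with a message reporting the count.
#'
#' @param records data.frame with columns `species`, `year`, `month`, `day`,
#'   `locality`, `county`, `collector` (one row per individual).
#' @return object of class `opp_events`: list with `events` (one row per
#'   sampling event: `list_id`, `locality`, `date`, `county`, `collector`,
#'   `year`, `L`, `records`, ordered by year, county, locality, collector)
#'   and `membership` (long table of `list_id`, `species`).
#' @export
build_lists <- function(records) {
  need <- c("species", "year", "locality", "county", "collector")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("record table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"month" %in% names(records)) records$month <- NA_integer_
  if (!"day" %in% names(records)) records$day <- NA_integer_

  bad <- rep(FALSE, nrow(records))
  for (f in need) {
    v <- records[[f]]
    bad <- bad | is.na(v) | (is.character(v) & !nzchar(trimws(as.character(v))))
  }
  if (any(bad)) {
    message("build_lists: rejecting ", sum(bad),
            " record row(s) with missing key fields")
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) {
    ev <- data.frame(list_id = character(), locality = character(),
                     date = character(), county = character(),
                     collector = character(), year = integer(),
                     L = integer(), records = integer())
    return(structure(list(events = ev,
                          membership = data.frame(list_id = character(),
                                                  species = character())),
                     class = "opp_events"))
  }

  records$.date <- record_date(records)
  key <- paste(records$locality, records$.date, records$collector, sep = "\r")
  first <- !duplicated(key)
  ev <- records[first, c("locality", "county", "collector", "year")]
  ev$date <- records$.date[first]
  kf <- factor(key, levels = key[first])
  ev$L <- as.integer(tapply(records$species, kf,
                            function(s) length(unique(s))))
  ev$records <- as.integer(tabulate(kf, nbins = nlevels(kf)))

  ord <- order(ev$year, ev$county, ev$locality, ev$collector, ev$date)
  ev <- ev[ord, c("locality", "date", "county", "collector", "year",
                  "L", "records")]
  ev$list_id <- sprintf("L%05d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  ev <- ev[, c("list_id", "locality", "date", "county", "collector",
               "year", "L", "records")]

  mem <- unique(data.frame(key = key, species = records$species,
                           stringsAsFactors = FALSE))
  key_sorted <- paste(ev$locality, ev$date, ev$collector, sep = "\r")
  mem$list_id <- ev$list_id[match(mem$key, key_sorted)]
  mem <- mem[order(mem$list_id, mem$species), c("list_id", "species")]
  rownames(mem) <- NULL

  structure(list(events = ev, membership = mem), class = "opp_events")
}

#' @export
print.opp_events <- function(x, ...) {
  cat("Sampling-event lists:", nrow(x$events), "events,",
      length(unique(x$membership$species)), "species,",
      sum(x$events$records), "records\n")
  if (nrow(x$events)) {
    cat("  years ", min(x$events$year), "-", max(x$events$year),
        ", mean list length ", round(mean(x$events$L), 2), "\n", sep = "")
  }
  invisible(x)
}

#' Drop short (likely incomplete) lists
#'
#' Lists with fewer than `min_L` species are treated as incomplete samples
#' of the fauna present and removed before modeling.
#'
#' @param ev an `opp_events` object.
#' @param min_L minimum list length retained (default 2).
#' @return the filtered `opp_events`.
#' @export
filter_events <- function(ev, min_L = 2) {
  stopifnot(inherits(ev, "opp_events"))
  keep <- ev$events$L >= min_L
  message("filter_events: retained ", sum(keep), " of ", length(keep),
          " events (dropped ", sum(!keep), " with L < ", min_L, ")")
  ev$events <- ev$events[keep, , drop = FALSE]
  ev$membership <- ev$membership[ev$membership$list_id %in%
                                   ev$events$list_id, , drop = FALSE]
  rownames(ev$events) <- rownames(ev$membership) <- NULL
  ev
}

#' Assemble an analysis dataset for one activity class
#'
#' Builds the modeling dataset: the events belonging to the class (an event
#' belongs to a class if it contains at least one species of that class, so
#' mixed lists join both classes), the species roster (species recorded in
#' at least `min_lists` of those events; rarer species are reported and
#' excluded), and the event-by-species 0/1 response matrix.
#'
#' @param ev an `opp_events` object (after [filter_events()]).
#' @param traits data.frame with columns `species` and `activity`
#'   ("diurnal"/"nocturnal"); required when `activity` is given.  Every
#'   species occurring in the events must have a trait row.
#' @param activity restrict to one class, or `NULL` to use all events and
#'   species (useful for calibration studies on simulated data).
#' @param min_lists roster inclusion threshold (default 10 lists).
#' @param species optional focal-species set: the roster is restricted to
#'   these labels (collections often record a broader fauna than the taxon
#'   under study; non-focal species still contribute to list length).
#' @return object of class `opp_dataset`: `activity`, `events`, `roster`,
#'   `response` (events x roster 0/1 matrix), `excluded` (species below the
#'   threshold with their list counts).
#' @export
as_analysis_dataset <- function(ev, traits = NULL, activity = NULL,
                                min_lists = 10, species = NULL) {
  stopifnot(inherits(ev, "opp_events"))
  mem <- ev$membership
  events <- ev$events
  if (!is.null(activity)) {
    if (is.null(traits)) stop("traits table required to split by activity")
    idx <- match(mem$species, traits$species)
    if (anyNA(idx))
      stop("species missing from trait table: ",
           paste(sort(unique(mem$species[is.na(idx)])), collapse = ", "))
    cls <- traits$activity[idx]
    in_class <- unique(mem$list_id[cls == activity])
    events <- events[events$list_id %in% in_class, , drop = FALSE]
    mem <- mem[mem$list_id %in% in_class & cls == activity, , drop = FALSE]
  }
  if (!is.null(species)) mem_focal <- mem[mem$species %in% species, ,
                                          drop = FALSE]
  else mem_focal <- mem
  counts <- table(mem_focal$species)
  roster <- sort(names(counts)[counts >= min_lists])
  excluded <- data.frame(species = names(counts)[counts < min_lists],
                         n_lists = as.integer(counts[counts < min_lists]))
  if (nrow(excluded))
    message("as_analysis_dataset", if (!is.null(activity)) paste0(" (", activity, ")"),
            ": excluding ", nrow(excluded), " species recorded in fewer than ",
            min_lists, " lists")
  resp <- matrix(0L, nrow(events), length(roster),
                 dimnames = list(events$list_id, roster))
  hit <- mem[mem$species %in% roster, , drop = FALSE]
  resp[cbind(match(hit$list_id, events$list_id),
             match(hit$species, roster))] <- 1L
  structure(list(activity = activity, events = events, roster = roster,
                 response = resp, excluded = excluded),
            class = "opp_dataset")
}

#' @export
print.opp_dataset <- function(x, ...) {
  cat("Analysis dataset",
      if (!is.null(x$activity)) paste0(" (", x$activity, ")"), ": ",
      nrow(x$events), " lists, ", length(x$roster),
      " rostered species (", nrow(x$excluded), " below threshold)\n",
      sep = "")
  invisible(x)
}

#' Split events into diurnal and nocturnal analysis datasets
#'
#' @inheritParams as_analysis_dataset
#' @return named list of two `opp_dataset` objects, `diurnal` and
#'   `nocturnal`.
#' @export
split_by_activity <- function(ev, traits, min_lists = 10, species = NULL) {
  list(diurnal = as_analysis_dataset(ev, traits, "diurnal", min_lists,
                                     species),
       nocturnal = as_analysis_dataset(ev, traits, "nocturnal", min_lists,
                                       species))
}
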