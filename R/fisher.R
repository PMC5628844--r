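#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact test by full hypergeometric enumeration with fixed margins.  The
#' two-tailed p-value follows the small-p-values convention: the sum of the
#' probabilities of every table (with the observed margins) whose point
#' probability is no greater than that of the observed table, ties included.
#' This is the convention under which the trait-trend tables reproduce their
#' published p-values; the alternative "double the one tail" definition does
#' not.  Point probabilities come from the hypergeometric mass function
#' evaluated in a numerically stable form.
#'
#' @param tab 2x2 matrix of nonnegative integer counts (rows: trait levels;
#'   columns: outcome levels).
#' @return object of class `opp_fisher`: `p_value`, `odds_ratio` (sample
#'   cross-product ratio), `table`.
#' @examples
#' fisher_exact(matrix(c(5, 1, 3, 6), 2)) # p = 595/5005
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative cell count")
  if (any(abs(tab - round(tab)) > 1e-8)) stop("non-integer cell count")
  tab <- round(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (min(r1, r2, c1, c2) == 0)
    stop("degenerate margins: every margin must be positive")

  a <- tab[1, 1]
  support <- max(0, c1 - r2):min(c1, r1)
  d <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(p_value = min(p, 1), odds_ratio = or, table = tab),
            class = "opp_fisher")
}

#' @export
print.opp_fisher <- function(x, ...) {
  cat("Two-tailed Fisher exact test\n")
  print(x$table)
  cat("odds ratio (cross-product):", format(x$odds_ratio, digits = 4),
      "  p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Trend-by-trait contingency table
#'
#' Cross-tabulates host-plant habit (tree/vine vs shrub/herb feeders)
#' against whether a species was classified as declining.  Crop-pest species
#' (whose trends track agricultural host availability rather than wild host
#' plants) can be excluded, and the comparison can be restricted to
#' summer-flying species -- the season by which parasitoid populations have
#' built up -- by dropping spring-only fliers.
#'
#' @param trends data.frame with `species` and `call` columns (e.g. the
#'   `trends` element of an [run_species_inference()] result).
#' @param traits data.frame with `species`, `host_habit`
#'   ("tree_vine"/"shrub_herb"), and optionally `activity`, `flight_period`
#'   ("spring"/"summer"), `crop_pest` (logical).
#' @param activity restrict to one activity class (default "nocturnal");
#'   `NULL` keeps all.
#' @param exclude_pests drop crop-pest species (default TRUE).
#' @param summer_only drop species flying only in spring (default FALSE).
#' @return 2x2 integer matrix (rows `tree_vine`, `shrub_herb`; columns
#'   `declined`, `not_declined`) with the excluded species recorded in
#'   attribute `"excluded"`.
#' @export
build_trend_table <- function(trends, traits, activity = "nocturnal",
                              exclude_pests = TRUE, summer_only = FALSE) {
  idx <- match(trends$species, traits$species)
  if (anyNA(idx))
    stop("species missing from trait table: ",
         paste(trends$species[is.na(idx)], collapse = ", "))
  d <- cbind(trends, traits[idx, setdiff(names(traits), "species"),
                            drop = FALSE])
  dropped <- character()
  note <- function(who, why) {
    if (length(who)) message("build_trend_table: dropping ",
                             length(who), " species (", why, "): ",
                             paste(who, collapse = ", "))
    c(dropped, who)
  }
  keep <- d$call %in% c("decline", "increase", "no_trend")
  dropped <- note(d$species[!keep], "insufficient data")
  d <- d[keep, , drop = FALSE]
  if (!is.null(activity) && "activity" %in% names(d)) {
    keep <- d$activity == activity
    dropped <- note(d$species[!keep], paste0("not ", activity))
    d <- d[keep, , drop = FALSE]
  }
  if (exclude_pests && "crop_pest" %in% names(d)) {
    keep <- !d$crop_pest
    dropped <- note(d$species[!keep], "crop pest")
    d <- d[keep, , drop = FALSE]
  }
  if (summer_only && "flight_period" %in% names(d)) {
    keep <- d$flight_period != "spring"
    dropped <- note(d$species[!keep], "spring-only flight")
    d <- d[keep, , drop = FALSE]
  }
  if (!nrow(d)) stop("no species left after filtering")
  stopifnot(all(d$host_habit %in% c("tree_vine", "shrub_herb")))
  tab <- matrix(0L, 2, 2, dimnames = list(c("tree_vine", "shrub_herb"),
                                          c("declined", "not_declined")))
  declined <- factor(ifelse(d$call == "decline", "declined", "not_declined"),
                     levels = colnames(tab))
  habit <- factor(d$host_habit, levels = rownames(tab))
  cnt <- table(habit, declined)
  tab[] <- as.integer(cnt)
  attr(tab, "excluded") <- dropped
  tab
}
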