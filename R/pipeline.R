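#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis.  Inputs are either a
#' simulation configuration (`simulation =`) or paths to record, trait and
#' climate CSV files.
#'
#' @param outdir output directory for stage artifacts (created if absent).
#' @param simulation optional `opp_sim_config`; when given, inputs are
#'   simulated and written to `outdir` first.
#' @param records,traits,climate input CSV paths (ignored when `simulation`
#'   is given).
#' @param activities which activity classes to analyze.
#' @param min_list_length shortest list retained (default 2).
#' @param min_lists_per_species roster inclusion threshold (default 10).
#' @param nodes quadrature nodes per fit (default 15).
#' @param evidence_ratio,dominance best-model-set thresholds.
#' @param ci_multiplier confidence-interval half-width multiplier.
#' @param optional_terms candidate optional fixed terms.
#' @param merge_map optional named vector of taxon merges.
#' @param region_labels optional: retain only records whose `region` column
#'   matches one of these labels before analysis (e.g. parasitoid-exposed
#'   areas only).
#' @param seed seed used when simulating inputs.
#' @return validated list of class `opp_pipeline_config`.
#' @export
pipeline_config <- function(outdir, simulation = NULL, records = NULL,
                            traits = NULL, climate = NULL,
                            activities = c("diurnal", "nocturnal"),
                            min_list_length = 2, min_lists_per_species = 10,
                            nodes = 15, evidence_ratio = 0.05,
                            dominance = 0.9, ci_multiplier = 1.96,
                            optional_terms = c("year", "bio6", "bio10", "bio18"),
                            merge_map = NULL, region_labels = NULL,
                            seed = 1) {
  stopifnot(min_list_length >= 1, min_lists_per_species >= 1, nodes >= 1,
            evidence_ratio > 0, evidence_ratio <= 1, ci_multiplier > 0)
  if (is.null(simulation) && (is.null(records) || is.null(traits) ||
                              is.null(climate)))
    stop("either a simulation config or record/trait/climate paths required")
  structure(as.list(environment()), class = "opp_pipeline_config")
}

#' Restrict records to labelled regions
#'
#' Supports comparisons between geographic subsets of the records (e.g.
#' areas exposed to an introduced parasitoid versus refuge areas): keeps
#' only rows whose region label is in `region_labels`.
#'
#' @param records record table with a `region` column (or the column named
#'   by `region_col`).
#' @param region_labels labels to keep.
#' @param region_col name of the label column (default "region").
#' @return the filtered record table.
#' @export
subset_records <- function(records, region_labels, region_col = "region") {
  if (!region_col %in% names(records))
    stop("record table has no '", region_col, "' column")
  keep <- records[[region_col]] %in% region_labels
  message("subset_records: retained ", sum(keep), " of ", length(keep),
          " records in region(s) ", paste(region_labels, collapse = ", "))
  records[keep, , drop = FALSE]
}

write_stage <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full trend-estimation pipeline
#'
#' Stages, in order: obtain inputs (simulate or read), derive bioclimatic
#' covariates, merge taxa, aggregate records into lists, drop short lists,
#' split into activity-class datasets, per-species multi-model inference,
#' trend classification, and trait-trend Fisher tests (nocturnal class).
#' Every stage writes its CSV artifact into `cfg$outdir` along with a run
#' manifest; rerunning with the same configuration reproduces the outputs
#' byte for byte.
#'
#' @param cfg an [pipeline_config()] object.
#' @return list of class `opp_pipeline`: `inference` (per activity class),
#'   `trends`, `fisher` (all-species and summer-restricted tests, when the
#'   nocturnal class was analyzed), `events`, `covariates`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "opp_pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()

  if (!is.null(cfg$simulation)) {
    cfg$simulation$seed <- cfg$seed
    sim <- simulate_records(cfg$simulation)
    records <- sim$records
    traits <- sim$traits
    climate <- sim$climate
    write_stage(records, cfg$outdir, "records.csv")
    write_stage(traits, cfg$outdir, "traits.csv")
    write_stage(climate, cfg$outdir, "climate.csv")
  } else {
    for (f in c("records", "traits", "climate"))
      if (!file.exists(cfg[[f]]))
        stop("input file not found: ", cfg[[f]], " (", f, ")")
    records <- read.csv(cfg$records)
    traits <- read.csv(cfg$traits)
    climate <- read.csv(cfg$climate)
    sim <- NULL
  }
  log_counts$records_in <- nrow(records)

  if (!is.null(cfg$region_labels))
    records <- subset_records(records, cfg$region_labels)
  records <- taxon_merge(records, cfg$merge_map)

  covars <- county_year_covariates(climate)
  write_stage(covars, cfg$outdir, "covariates.csv")

  ev <- build_lists(records)
  log_counts$lists_built <- nrow(ev$events)
  ev <- filter_events(ev, cfg$min_list_length)
  log_counts$lists_retained <- nrow(ev$events)
  write_stage(ev$events, cfg$outdir, "events.csv")

  ## a `focal` trait column restricts the modeled roster to the taxon of
  ## interest (non-focal species still count toward list length)
  focal <- if ("focal" %in% names(traits)) traits$species[traits$focal]
  inference <- list()
  trends <- list()
  for (cls in cfg$activities) {
    ds <- as_analysis_dataset(ev, traits, cls, cfg$min_lists_per_species,
                              species = focal)
    if (!length(ds$roster)) {
      message("run_pipeline: no rostered species for class ", cls)
      next
    }
    write_stage(cbind(list_id = rownames(ds$response),
                      as.data.frame(ds$response)),
                cfg$outdir, paste0("response_", cls, ".csv"))
    inf <- run_species_inference(ds, covars,
                                 optional_terms = cfg$optional_terms,
                                 nodes = cfg$nodes,
                                 ratio = cfg$evidence_ratio,
                                 dominance = cfg$dominance,
                                 z = cfg$ci_multiplier)
    write_stage(inf$candidates, cfg$outdir, paste0("candidates_", cls, ".csv"))
    write_stage(inf$averaged, cfg$outdir, paste0("coefficients_", cls, ".csv"))
    write_stage(inf$trends, cfg$outdir, paste0("trends_", cls, ".csv"))
    inference[[cls]] <- inf
    trends[[cls]] <- cbind(activity = cls, inf$trends)
  }
  trends <- if (length(trends))
    do.call(rbind, c(trends, list(make.row.names = FALSE))) else NULL

  fisher <- NULL
  if ("nocturnal" %in% names(inference)) {
    noct <- inference$nocturnal$trends
    fisher <- tryCatch({
      tab_all <- build_trend_table(noct, traits, activity = "nocturnal")
      tab_summer <- build_trend_table(noct, traits, activity = "nocturnal",
                                      summer_only = TRUE)
      list(all = fisher_exact(tab_all), summer = fisher_exact(tab_summer))
    }, error = function(e) {
      message("run_pipeline: trait test skipped (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(fisher)) {
      ftab <- data.frame(
        test = c("host_habit_all", "host_habit_summer"),
        tree_vine_declined = c(fisher$all$table[1, 1], fisher$summer$table[1, 1]),
        tree_vine_not = c(fisher$all$table[1, 2], fisher$summer$table[1, 2]),
        shrub_herb_declined = c(fisher$all$table[2, 1], fisher$summer$table[2, 1]),
        shrub_herb_not = c(fisher$all$table[2, 2], fisher$summer$table[2, 2]),
        odds_ratio = c(fisher$all$odds_ratio, fisher$summer$odds_ratio),
        p_value = c(fisher$all$p_value, fisher$summer$p_value))
      write_stage(ftab, cfg$outdir, "fisher_tests.csv")
    }
  }

  manifest <- c(
    list(package_version = as.character(packageVersion("opptrend")),
         seed = cfg$seed,
         min_list_length = cfg$min_list_length,
         min_lists_per_species = cfg$min_lists_per_species,
         nodes = cfg$nodes, evidence_ratio = cfg$evidence_ratio,
         dominance = cfg$dominance, ci_multiplier = cfg$ci_multiplier,
         optional_terms = paste(cfg$optional_terms, collapse = ","),
         activities = paste(cfg$activities, collapse = ",")),
    log_counts)
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))

  structure(list(inference = inference, trends = trends, fisher = fisher,
                 events = ev, covariates = covars, simulation = sim,
                 manifest = manifest),
            class = "opp_pipeline")
}

#' @export
print.opp_pipeline <- function(x, ...) {
  cat("Trend-estimation pipeline run\n")
  cat("  lists analyzed:", x$manifest$lists_retained, "of",
      x$manifest$lists_built, "built\n")
  if (!is.null(x$trends)) print(table(x$trends$activity, x$trends$call))
  if (!is.null(x$fisher))
    cat("  Fisher p (host habit, all / summer):",
        format(x$fisher$all$p_value, digits = 3), "/",
        format(x$fisher$summer$p_value, digits = 3), "\n")
  invisible(x)
}
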