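OPT_TERMS <- c("year", "bio6", "bio10", "bio18")
MANDATORY_TERMS <- c("logL", "records")
TERM_ORDER <- c("year", "logL", "records", "bio6", "bio10", "bio18")

#' Candidate model specification
#'
#' Every candidate model carries the intercept, the two recorder-effort
#' controls (`logL`, `records`) and the county random intercept; candidates
#' differ only in which of the optional terms (`year`, `bio6`, `bio10`,
#' `bio18`) they include.
#'
#' @param optional character vector drawn from
#'   `c("year", "bio6", "bio10", "bio18")`.
#' @return object of class `opp_model_spec` with fields `terms` (fixed-term
#'   columns in canonical order), `optional`, `label`, and `group`
#'   (`"county"`).
#' @export
model_spec <- function(optional = character()) {
  bad <- setdiff(optional, OPT_TERMS)
  if (length(bad)) stop("unknown optional term(s): ", paste(bad, collapse = ", "))
  terms <- intersect(TERM_ORDER, c(MANDATORY_TERMS, optional))
  structure(list(terms = terms,
                 optional = intersect(TERM_ORDER, optional),
                 label = paste(terms, collapse = "+"),
                 group = "county"),
            class = "opp_model_spec")
}

#' All-subsets candidate model set
#'
#' @param optional the optional terms to toggle (default all four, giving
#'   `2^4 = 16` candidates).  The effort-only null model is always included.
#' @return list of [model_spec()] objects in stable lexicographic order of
#'   the included-term labels (used to break AICc ties downstream).
#' @export
enumerate_models <- function(optional = OPT_TERMS) {
  optional <- intersect(TERM_ORDER, unique(optional))
  n <- length(optional)
  specs <- lapply(seq_len(2^n) - 1L, function(mask) {
    model_spec(optional[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
  })
  specs[order(vapply(specs, `[[`, "", "label"))]
}

#' Standardized design for one analysis dataset
#'
#' Joins the bioclimatic covariates onto the dataset's events and
#' standardizes all six continuous predictors (`year`, `logL = log(L)`
#' natural log, `records`, `bio6`, `bio10`, `bio18`) once per dataset, so
#' every species fitted from it shares the same scale.  The standardization
#' constants are stored for mapping coefficients back to natural units.
#'
#' @param dataset an `opp_dataset` from [as_analysis_dataset()].
#' @param covariates county-year table from [county_year_covariates()].
#' @return object of class `opp_design`: standardized predictor matrix `X`,
#'   `center`/`scale`, `group` (county factor), `response` matrix, `roster`.
#' @export
build_design <- function(dataset, covariates) {
  stopifnot(inherits(dataset, "opp_dataset"))
  ev <- attach_covariates(dataset$events, covariates)
  raw <- cbind(year = ev$year, logL = log(ev$L), records = ev$records,
               bio6 = ev$bio6, bio10 = ev$bio10, bio18 = ev$bio18)
  std <- standardize_columns(raw)
  structure(list(X = std$x, center = std$center, scale = std$scale,
                 group = factor(norm_label(ev$county)),
                 response = dataset$response, roster = dataset$roster,
                 list_id = ev$list_id, activity = dataset$activity),
            class = "opp_design")
}

#' Fit one candidate model for one species
#'
#' Thin wrapper around [glmm_ml()]: selects the spec's standardized columns,
#' prepends the intercept, takes the species' 0/1 reporting-rate column as
#' response and the county factor as grouping.
#'
#' @param design an `opp_design` from [build_design()].
#' @param species a rostered species label.
#' @param spec an `opp_model_spec` (default: the full model).
#' @param nodes quadrature nodes (default 15).
#' @param ... passed on to [glmm_ml()].
#' @return an `opp_fit` (with the spec label attached as `$spec`).
#' @export
fit_glmm <- function(design, species, spec = model_spec(OPT_TERMS),
                     nodes = 15, ...) {
  stopifnot(inherits(design, "opp_design"), inherits(spec, "opp_model_spec"))
  if (!species %in% colnames(design$response))
    stop("species not in roster: ", species)
  X <- cbind("(intercept)" = 1, design$X[, spec$terms, drop = FALSE])
  fit <- glmm_ml(design$response[, species], X, design$group,
                 nodes = nodes, ...)
  fit$species <- species
  fit$spec <- spec
  fit
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` with `delta` relative to
#' the best (smallest) AICc; computed after subtracting the minimum, so very
#' large deltas underflow gracefully to zero weight.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return numeric weights summing to 1.
#' @examples
#' akaike_weights(c(100, 102)) # 0.731, 0.269
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Evidence-ratio best-model set
#'
#' If one model is overwhelmingly supported (weight at or above
#' `dominance`), it is retained alone.  Otherwise all models whose weight is
#' at least `ratio` times the best weight (the 0.05 evidence-ratio rule) are
#' retained.
#'
#' @param weights Akaike weights.
#' @param ratio evidence ratio threshold (default 0.05).
#' @param dominance single-model dominance threshold (default 0.9).
#' @return logical vector marking retained models.
#' @export
best_model_set <- function(weights, ratio = 0.05, dominance = 0.9) {
  stopifnot(ratio > 0, ratio <= 1)
  if (max(weights) >= dominance) {
    retained <- seq_along(weights) == which.max(weights)
  } else {
    retained <- weights >= ratio * max(weights)
  }
  retained
}

#' Conditional model averaging
#'
#' Averages each coefficient only over the models in which its term appears,
#' with weights renormalized over those models.  The model-averaged standard
#' error combines within-model variance and between-model spread:
#' `SE_t = sum_i w_i * sqrt(SE_i^2 + (beta_i - beta_bar)^2)`.
#'
#' @param estimates models x terms matrix of coefficients, `NA` where a term
#'   is absent from a model.
#' @param ses matching matrix of standard errors.
#' @param weights per-model weights (typically the retained models' Akaike
#'   weights; they need not sum to 1).
#' @return data.frame with one row per term present in at least one model:
#'   `term`, `estimate`, `se`, `n_models`, `weight_sum` (summed
#'   unrenormalized weight of the containing models).
#' @export
model_average <- function(estimates, ses, weights) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  stopifnot(identical(dim(estimates), dim(ses)),
            nrow(estimates) == length(weights))
  out <- lapply(colnames(estimates), function(term) {
    b <- estimates[, term]
    has <- !is.na(b)
    if (!any(has)) return(NULL)
    w <- weights[has] / sum(weights[has])
    bbar <- sum(w * b[has])
    se <- sum(w * sqrt(ses[has, term]^2 + (b[has] - bbar)^2))
    data.frame(term = term, estimate = bbar, se = se,
               n_models = sum(has), weight_sum = sum(weights[has]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify a trend from the averaged year coefficient
#'
#' The 95% interval is `estimate +/- z * se`; a species is declining when
#' the whole interval lies below zero, increasing when it lies above zero,
#' and trendless when the interval straddles zero.  A missing estimate
#' (e.g. the year term absent from every retained model) yields
#' `"insufficient"`.
#'
#' @param estimate,se averaged year coefficient and standard error
#'   (vectorized).
#' @param z interval half-width multiplier (default 1.96).
#' @return data.frame with `estimate`, `ci_low`, `ci_high`, `call`.
#' @export
classify_trend <- function(estimate, se, z = 1.96) {
  lo <- estimate - z * se
  hi <- estimate + z * se
  call <- ifelse(is.na(estimate) | is.na(se), "insufficient",
          ifelse(hi < 0, "decline",
          ifelse(lo > 0, "increase", "no_trend")))
  data.frame(estimate = estimate, ci_low = lo, ci_high = hi, call = call)
}

#' Collinearity diagnostics for a design
#'
#' Variance inflation factors (`1/(1 - R^2)` from regressing each predictor
#' on the others) and pairwise Spearman rank correlations among the
#' continuous predictors.
#'
#' @param x an `opp_design` or a numeric predictor matrix.
#' @param vif_threshold VIFs at or above this are flagged (default 5).
#' @return list of class `opp_collinearity`: `vif` (named), `spearman`
#'   (matrix), `flagged` (term names).
#' @export
collinearity_report <- function(x, vif_threshold = 5) {
  X <- if (inherits(x, "opp_design")) x$X else as.matrix(x)
  stopifnot(ncol(X) >= 2)
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  structure(list(vif = vif,
                 spearman = cor(X, method = "spearman"),
                 flagged = names(vif)[vif >= vif_threshold],
                 vif_threshold = vif_threshold),
            class = "opp_collinearity")
}

#' @export
print.opp_collinearity <- function(x, ...) {
  cat("Collinearity diagnostics\n  VIF:\n")
  print(round(x$vif, 3))
  cat("  max |Spearman rho| off-diagonal:",
      round(max(abs(x$spearman[upper.tri(x$spearman)])), 3), "\n")
  if (length(x$flagged))
    cat("  flagged (VIF >=", x$vif_threshold, "):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Multi-model inference for every rostered species
#'
#' The full procedure, per species: fit all candidate models (all subsets of
#' the optional terms on top of the mandatory effort controls), drop
#' non-converged fits with a warning, rank by AICc, compute Akaike weights,
#' retain the evidence-ratio best-model set, conditionally average
#' coefficients, and classify the trend from the averaged year coefficient.
#'
#' @param dataset an `opp_dataset`.
#' @param covariates county-year covariate table.
#' @param optional_terms optional fixed terms to toggle (default all four).
#' @param nodes quadrature nodes per fit.
#' @param ratio,dominance evidence-ratio and dominance thresholds for
#'   [best_model_set()].
#' @param z confidence-interval multiplier for [classify_trend()].
#' @return object of class `opp_inference`: `candidates` (one row per
#'   species x model: terms, n, k, logLik, AICc, delta, weight, retained),
#'   `averaged` (long table of conditional model-averaged coefficients),
#'   `trends` (species, estimate, ci_low, ci_high, call),
#'   `collinearity`, `design`.
#' @export
run_species_inference <- function(dataset, covariates,
                                  optional_terms = OPT_TERMS, nodes = 15,
                                  ratio = 0.05, dominance = 0.9, z = 1.96) {
  design <- build_design(dataset, covariates)
  specs <- enumerate_models(optional_terms)
  cand_all <- list()
  avg_all <- list()
  trend_all <- list()

  for (sp in design$roster) {
    fits <- lapply(specs, function(s) fit_glmm(design, sp, s, nodes = nodes))
    ok <- vapply(fits, function(f) isTRUE(f$converged) && f$se_ok, logical(1))
    if (!all(ok))
      warning(sum(!ok), " non-converged candidate model(s) dropped for ",
              sp, call. = FALSE)
    fits <- fits[ok]
    if (!length(fits)) {
      trend_all[[sp]] <- cbind(species = sp,
                               classify_trend(NA_real_, NA_real_, z))
      next
    }
    a <- vapply(fits, `[[`, numeric(1), "aicc")
    w <- akaike_weights(a)
    ## stable ordering: AICc, then spec label for exact ties
    lab <- vapply(fits, function(f) f$spec$label, "")
    ord <- order(a, lab)
    fits <- fits[ord]; a <- a[ord]; w <- w[ord]; lab <- lab[ord]
    retained <- best_model_set(w, ratio, dominance)

    cand_all[[sp]] <- data.frame(
      species = sp, model = lab,
      n = vapply(fits, `[[`, numeric(1), "n_obs"),
      k = vapply(fits, `[[`, numeric(1), "k_params"),
      logLik = vapply(fits, `[[`, numeric(1), "log_marginal_likelihood"),
      aicc = a, delta = a - min(a), weight = w, retained = retained)

    kept <- fits[retained]
    terms <- c("(intercept)", intersect(TERM_ORDER,
               unique(unlist(lapply(kept, function(f) f$spec$terms)))))
    est <- matrix(NA_real_, length(kept), length(terms),
                  dimnames = list(NULL, terms))
    ses <- est
    for (i in seq_along(kept)) {
      cf <- kept[[i]]$coefficients
      est[i, names(cf)] <- cf
      ses[i, names(cf)] <- kept[[i]]$se
    }
    avg <- model_average(est, ses, w[retained])
    avg_all[[sp]] <- cbind(species = sp, avg)

    yr <- avg[avg$term == "year", ]
    tr <- if (nrow(yr)) classify_trend(yr$estimate, yr$se, z)
          else classify_trend(NA_real_, NA_real_, z)
    trend_all[[sp]] <- cbind(species = sp, tr)
  }

  rbind_all <- function(l)
    if (length(l)) do.call(rbind, c(l, list(make.row.names = FALSE))) else NULL
  structure(list(
    activity = dataset$activity,
    candidates = rbind_all(cand_all),
    averaged = rbind_all(avg_all),
    trends = rbind_all(trend_all),
    collinearity = collinearity_report(design),
    design = design
  ), class = "opp_inference")
}

#' @export
print.opp_inference <- function(x, ...) {
  cat("Multi-model inference",
      if (!is.null(x$activity)) paste0(" (", x$activity, ")"),
      ": ", length(unique(x$trends$species)), " species\n", sep = "")
  print(table(x$trends$call))
  invisible(x)
}
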