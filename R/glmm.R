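#' Standardize design columns to zero mean and unit standard deviation
#'
#' Centers each column by its mean and scales by its standard deviation
#' (denominator `n - 1`), storing the constants so coefficients estimated on
#' the standardized scale can be mapped back to natural units.  When `center`
#' and `scale` are supplied (e.g. to standardize new data with constants from
#' a reference dataset) they are used as-is.
#'
#' @param x numeric matrix (columns are predictors).
#' @param center,scale optional named numeric vectors of pre-computed
#'   constants, one per column of `x`.
#' @return list with elements `x` (standardized matrix), `center`, `scale`.
#' @examples
#' standardize_columns(cbind(a = c(1, 2, 3)))$x
#' @export
standardize_columns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, sd)
  bad <- colnames(x)[!is.finite(scale) | scale <= 0]
  if (length(bad))
    stop("cannot standardize constant (zero-SD) column(s): ",
         paste(bad, collapse = ", "))
  xs <- sweep(sweep(x, 2, center[colnames(x)]), 2, scale[colnames(x)], "/")
  list(x = xs, center = center[colnames(x)], scale = scale[colnames(x)])
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects, intercept, and the
#'   random-effect variance each count one).
#' @param n number of observations (rows of the fitted response vector).
#' @return numeric AICc value.
#' @examples
#' aicc(-10, 3, 20) # 27.5
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

## Gauss-Hermite nodes/weights for weight function exp(-x^2).  A single
## node (x = 0, w = sqrt(pi)) reproduces the Laplace approximation.
gh_rule <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  r <- pracma::gaussHermite(n)
  list(x = r$x, w = r$w)
}

as_group_index <- function(group) {
  f <- factor(group)
  list(index = as.integer(f) - 1L, levels = levels(f), n = nlevels(f))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates the log marginal likelihood of a Bernoulli/logit model with one
#' Gaussian random intercept per group, the intercept integrated out by
#' adaptive Gauss-Hermite quadrature.  The integral factorizes across groups;
#' each factor is a one-dimensional integral of the group's conditional
#' Bernoulli likelihood against the normal density of the group effect.  With
#' `nodes = 1` the rule collapses to the Laplace approximation; with
#' `sigma = 0` the function returns the ordinary logistic log-likelihood.
#'
#' @param beta fixed-effect coefficients, one per column of `X`.
#' @param sigma random-effect standard deviation (`>= 0`).
#' @param y 0/1 response vector.
#' @param X design matrix (include an intercept column explicitly).
#' @param group grouping factor (one random intercept per level).
#' @param nodes number of quadrature nodes (1 = Laplace).
#' @return the log marginal likelihood (a scalar).
#' @export
log_marginal_likelihood <- function(beta, sigma, y, X, group, nodes = 15) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(beta) == ncol(X), sigma >= 0)
  if (sigma < 1e-10)
    return(bern_loglik_cpp(beta, as.numeric(y), X, FALSE)$loglik)
  g <- as_group_index(group)
  r <- gh_rule(nodes)
  agq_loglik_cpp(beta, log(sigma), as.numeric(y), X, g$index, g$n,
                 r$x, r$w, FALSE)$loglik
}

## Objective/gradient closures over (beta, log_sigma); the last element of
## par is log(sigma) unless sigma is fixed at zero.
make_objective <- function(y, X, group, nodes, sigma_zero) {
  g <- as_group_index(group)
  r <- gh_rule(nodes)
  y <- as.numeric(y)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    val <- if (sigma_zero) {
      bern_loglik_cpp(par, y, X, TRUE)
    } else {
      p <- length(par) - 1L
      agq_loglik_cpp(par[seq_len(p)], par[p + 1L], y, X, g$index, g$n,
                     r$x, r$w, TRUE)
    }
    cache$key <- key
    cache$val <- val
    val
  }
  list(
    fn = function(par) -eval_at(par)$loglik,
    gr = function(par) -eval_at(par)$grad,
    loglik = function(par) eval_at(par)$loglik
  )
}

## Finite-difference Hessian of the negative log-likelihood, by central
## differences of the analytic gradient.
fd_hessian <- function(gr, par, h_rel = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- h_rel * max(1, abs(par[j]))
    e <- numeric(p); e[j] <- h
    H[, j] <- (gr(par + e) - gr(par - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Maximum-likelihood fit of the random-intercept logistic model
#'
#' Maximizes the marginal likelihood evaluated by
#' [log_marginal_likelihood()] over the fixed-effect coefficients and
#' `log(sigma)`, using BFGS with the analytic quadrature gradient followed by
#' Newton polishing steps.  Standard errors come from the inverse of the
#' negative Hessian of the marginal log-likelihood at the optimum.
#'
#' This is the computational engine behind [fit_glmm()]; it works on raw
#' matrices and knows nothing about standardization or model specs.
#'
#' @param y 0/1 response vector.
#' @param X design matrix including the intercept column.
#' @param group grouping factor for the random intercept.
#' @param nodes quadrature nodes (1 = Laplace; default 15).
#' @param sigma_zero fit with the random-effect SD fixed at exactly zero
#'   (ordinary logistic regression on the same code path).
#' @param start optional start values `c(beta, log_sigma)`.
#' @param control list with elements `maxit` (default 500), `grad_tol`
#'   (default 1e-6 on the max-norm of the score) and `reltol` (default 1e-10
#'   on the relative log-likelihood change).
#' @return object of class `opp_fit`; see [fit_glmm()] for the fields.
#' @export
glmm_ml <- function(y, X, group, nodes = 15, sigma_zero = FALSE,
                    start = NULL, control = list()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(p))
  npar <- if (sigma_zero) p else p + 1L
  if (length(y) < npar + 2)
    stop("too few observations (", length(y), ") for ", npar, " parameters")
  ctl <- modifyList(list(maxit = 500L, grad_tol = 1e-6, reltol = 1e-10),
                    control)

  obj <- make_objective(y, X, group, nodes, sigma_zero)
  if (is.null(start)) {
    ybar <- min(max(mean(y), 1e-3), 1 - 1e-3)
    start <- c(qlogis(ybar), rep(0, p - 1), if (!sigma_zero) log(0.5))
  }
  lower <- c(rep(-Inf, p), if (!sigma_zero) -15)
  upper <- c(rep(Inf, p), if (!sigma_zero) 5)
  opt <- optim(start, obj$fn, obj$gr, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = ctl$maxit, factr = 1e4))
  par <- opt$par

  ## Newton polish: drives the score to (near) machine zero so the stated
  ## gradient tolerance is actually met, and yields the Hessian for SEs.
  at_lower <- !sigma_zero && par[npar] <= lower[npar] + 1e-8
  free <- if (at_lower) seq_len(p) else seq_len(npar)
  H_free <- NULL
  for (it in seq_len(12)) {
    gr <- obj$gr(par)
    if (max(abs(gr[free])) < 1e-9) break
    H_free <- fd_hessian(function(q) {
      full <- par; full[free] <- q; obj$gr(full)[free]
    }, par[free])
    step <- tryCatch(solve(H_free, gr[free]), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- obj$fn(par)
    for (half in 0:10) {
      cand <- par
      cand[free] <- par[free] - step / 2^half
      if (!sigma_zero) cand[npar] <- min(max(cand[npar], lower[npar]), upper[npar])
      if (obj$fn(cand) <= f0 + 1e-12) { par <- cand; break }
    }
    at_lower <- !sigma_zero && par[npar] <= lower[npar] + 1e-8
    free <- if (at_lower) seq_len(p) else seq_len(npar)
  }

  gr <- obj$gr(par)
  grad_norm <- max(abs(gr[free]))
  loglik <- obj$loglik(par)
  converged <- grad_norm < ctl$grad_tol ||
    (opt$convergence == 0 && grad_norm < 1e-3)

  block_vcov <- function(idx) {
    H <- fd_hessian(function(q) {
      full <- par; full[idx] <- q; obj$gr(full)[idx]
    }, par[idx])
    v <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(v) && all(diag(v) > 0)) v else NULL
  }
  se <- rep(NA_real_, npar)
  vcov <- matrix(NA_real_, npar, npar)
  used <- free
  vcov_free <- block_vcov(free)
  if (is.null(vcov_free) && length(free) > p) {
    ## sigma near zero leaves the log-sd direction numerically flat; fall
    ## back to the fixed-effect block with sigma profiled at its estimate
    used <- seq_len(p)
    vcov_free <- block_vcov(used)
  }
  se_ok <- !is.null(vcov_free)
  if (se_ok) {
    vcov[used, used] <- vcov_free
    se[used] <- sqrt(diag(vcov_free))
  }

  sigma <- if (sigma_zero) 0 else exp(par[npar])
  if (!sigma_zero && sigma < 1e-6) sigma <- 0
  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  k <- p + 1L  # random-effect variance counts one parameter
  if (sigma_zero) k <- p
  n <- length(y)

  structure(list(
    coefficients = beta,
    se = setNames(se[seq_len(p)], colnames(X)),
    vcov = vcov[seq_len(p), seq_len(p), drop = FALSE],
    random_effect_sd = sigma,
    random_effect_sd_se = if (sigma_zero || sigma == 0) NA_real_
                          else se[npar] * sigma,  # delta method from log scale
    log_marginal_likelihood = loglik,
    n_obs = n, k_params = k,
    aicc = if (n > k + 1) aicc(loglik, k, n) else NA_real_,
    converged = converged, se_ok = se_ok,
    grad_norm = grad_norm, iterations = opt$counts[["function"]],
    nodes = nodes, sigma_zero = sigma_zero
  ), class = "opp_fit")
}

#' @export
print.opp_fit <- function(x, ...) {
  cat("Random-intercept logistic fit (adaptive Gauss-Hermite, ",
      x$nodes, " node", if (x$nodes > 1) "s", ")\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  cat("random-effect sd:", format(x$random_effect_sd, digits = 4),
      "  logLik:", format(x$log_marginal_likelihood, digits = 8),
      "  AICc:", format(x$aicc, digits = 8), "\n")
  cat("n =", x$n_obs, " k =", x$k_params,
      " converged:", x$converged, " max|score| =",
      format(x$grad_norm, digits = 3), "\n")
  invisible(x)
}

#' @export
logLik.opp_fit <- function(object, ...) {
  structure(object$log_marginal_likelihood, df = object$k_params,
            nobs = object$n_obs, class = "logLik")
}

#' Map standardized-scale coefficients to natural units
#'
#' Coefficients are estimated on the standardized predictor scale.  For a
#' predictor with standardization constants (m, s) the natural-scale slope is
#' `beta/s`, and the natural-scale intercept is
#' `alpha - sum(beta_j m_j / s_j)`.  Standard errors are propagated through
#' the same linear map using the fit's coefficient covariance.
#'
#' @param fit an `opp_fit` whose design columns (beyond the intercept) were
#'   standardized with `center`/`scale`.
#' @param center,scale named constants for the non-intercept columns, as
#'   stored by [standardize_columns()] (or an `opp_design`).
#' @return data.frame with natural-scale `estimate` and `se` per term.
#' @export
coef_natural <- function(fit, center, scale) {
  terms <- names(fit$coefficients)
  slopes <- setdiff(terms, "(intercept)")
  stopifnot(all(slopes %in% names(center)), all(slopes %in% names(scale)))
  p <- length(terms)
  ## rows of M give natural-scale coefficients as linear maps of fitted ones
  M <- diag(1 / c(1, scale[slopes]))
  M[1, ] <- c(1, -center[slopes] / scale[slopes])
  est <- drop(M %*% fit$coefficients)
  V <- M %*% fit$vcov %*% t(M)
  data.frame(term = terms, estimate = est, se = sqrt(pmax(diag(V), 0)),
             row.names = NULL)
}
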