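# Independent oracles used to cross-check the package's own numerics.
# These deliberately use different algorithms than the implementation.

# Logistic regression by hand-coded iteratively-reweighted least squares.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  beta
}

# Marginal log-likelihood by brute-force non-adaptive quadrature: a 201-node
# Gauss-Hermite rule centred at the prior (not at the conditional mode), so
# it shares no code path with the adaptive implementation.
brute_marginal_loglik <- function(beta, sigma, y, X, group, n_nodes = 201) {
  r <- pracma::gaussHermite(n_nodes)
  eta0 <- drop(as.matrix(X) %*% beta)
  ll <- 0
  for (g in unique(group)) {
    idx <- group == g
    contrib <- vapply(r$x, function(x) {
      b <- sqrt(2) * sigma * x
      eta <- eta0[idx] + b
      sum(ifelse(y[idx] == 1, -log1p(exp(-eta)), -log1p(exp(eta))))
    }, numeric(1))
    m <- max(log(r$w) + contrib)
    ll <- ll + m + log(sum(exp(log(r$w) + contrib - m))) - 0.5 * log(pi)
  }
  ll
}

# Same integral via base R's adaptive quadrature, as a second opinion.
integrate_marginal_loglik <- function(beta, sigma, y, X, group) {
  eta0 <- drop(as.matrix(X) %*% beta)
  ll <- 0
  for (g in unique(group)) {
    idx <- group == g
    f <- function(bv) vapply(bv, function(b) {
      p <- plogis(eta0[idx] + b)
      exp(sum(ifelse(y[idx] == 1, log(p), log1p(-p)))) * dnorm(b, 0, sigma)
    }, numeric(1))
    ll <- ll + log(integrate(f, -8 * sigma, 8 * sigma,
                             rel.tol = 1e-12)$value)
  }
  ll
}

# Two-tailed Fisher exact p by full enumeration with exact binomial
# coefficients (choose()), independent of dhyper.
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) / choose(N, c1)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Small mixed binary dataset generated without touching package code.
toy_mixed_data <- function(seed, G = 5, npg = 25, beta = c(-0.3, 0.8),
                           sigma = 0.7) {
  set.seed(seed)
  g <- rep(seq_len(G), each = npg)
  x <- rnorm(G * npg)
  X <- cbind(1, x)
  b <- rnorm(G, 0, sigma)
  y <- rbinom(G * npg, 1, plogis(drop(X %*% beta) + b[g]))
  list(y = y, X = X, group = g)
}

# A tiny record table with a known event structure, used by list tests.
toy_records <- function() {
  data.frame(
    species = c("a", "a", "b", "a", "c", "c", "d", "e"),
    year = c(1950, 1950, 1950, 1950, 1960, 1960, 1960, 1970),
    month = c(6, 6, 6, 6, 7, 7, 7, NA),
    day = c(1, 1, 1, 1, 2, 2, 2, NA),
    locality = c("x_site_01", "x_site_01", "x_site_01", "x_site_01",
                 "y_site_02", "y_site_02", "y_site_02", "x_site_01"),
    county = c("x", "x", "x", "x", "y", "y", "y", "x"),
    collector = c("c1", "c1", "c1", "c2", "c1", "c1", "c1", "c1"))
}
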