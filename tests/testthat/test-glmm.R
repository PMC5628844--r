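test_that("standardization centers, scales with n-1, and stores constants", {
  s <- standardize_columns(cbind(a = c(1, 2, 3)))
  expect_equal(drop(s$x), c(-1, 0, 1))
  expect_equal(unname(s$scale), 1)  # sd with denominator n-1
  # idempotence on an already-standardized column
  s2 <- standardize_columns(s$x)
  expect_equal(s2$x, s$x, tolerance = 1e-12)
  expect_error(standardize_columns(cbind(ok = 1:3, flat = rep(2, 3))),
               "flat")
  # supplied constants are honoured (new data on a reference scale)
  s3 <- standardize_columns(cbind(a = c(10, 20)), center = c(a = 0),
                            scale = c(a = 10))
  expect_equal(drop(s3$x), c(1, 2))
})

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_equal(aicc(0, 0, 10), 0)
  # large-n limit approaches plain AIC
  expect_equal(aicc(-50, 4, 1e8), -2 * -50 + 2 * 4, tolerance = 1e-5)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("marginal likelihood reduces to plain Bernoulli when sigma = 0", {
  expect_equal(log_marginal_likelihood(0, 0, 1, matrix(1), 1), log(0.5),
               tolerance = 1e-12)
  d <- toy_mixed_data(11)
  beta <- c(-0.2, 0.5)
  plain <- sum(ifelse(d$y == 1, log(plogis(drop(d$X %*% beta))),
                      log1p(-plogis(drop(d$X %*% beta)))))
  expect_equal(log_marginal_likelihood(beta, 0, d$y, d$X, d$group), plain,
               tolerance = 1e-12)
})

test_that("adaptive quadrature matches brute-force integration", {
  for (seed in 1:3) {
    d <- toy_mixed_data(seed, G = 3, npg = 5)
    for (sg in c(0.3, 0.7)) {
      a15 <- log_marginal_likelihood(c(-0.2, 0.6), sg, d$y, d$X, d$group, 15)
      br <- brute_marginal_loglik(c(-0.2, 0.6), sg, d$y, d$X, d$group)
      expect_equal(a15, br, tolerance = 1e-8)
      # second opinion from base R adaptive quadrature
      expect_equal(a15, integrate_marginal_loglik(c(-0.2, 0.6), sg, d$y,
                                                  d$X, d$group),
                   tolerance = 1e-8)
    }
  }
})

test_that("Laplace is close to 15-node quadrature and nodes converge", {
  d <- toy_mixed_data(5, G = 6, npg = 20)
  beta <- c(-0.1, 0.7)
  ref <- brute_marginal_loglik(beta, 0.7, d$y, d$X, d$group)
  l1 <- log_marginal_likelihood(beta, 0.7, d$y, d$X, d$group, nodes = 1)
  expect_equal(l1, ref, tolerance = 1e-3)
  errs <- vapply(c(1, 3, 7, 15), function(k)
    abs(log_marginal_likelihood(beta, 0.7, d$y, d$X, d$group, k) - ref),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-12))  # non-increasing error in nodes
})

test_that("marginal likelihood is invariant to group relabeling", {
  d <- toy_mixed_data(9)
  l1 <- log_marginal_likelihood(c(0.1, 0.4), 0.6, d$y, d$X, d$group)
  relab <- c(30, 10, 50, 20, 40)[d$group]
  l2 <- log_marginal_likelihood(c(0.1, 0.4), 0.6, d$y, d$X, relab)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("sigma = 0 fit reproduces hand-coded IRLS logistic regression", {
  d <- toy_mixed_data(21, sigma = 0)
  fit <- glmm_ml(d$y, d$X, d$group, sigma_zero = TRUE)
  oracle <- irls_logistic(d$X, d$y)
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-6)
  expect_true(fit$converged)
})

test_that("duplicating every row leaves estimates fixed and scales SEs by sqrt(2)", {
  d <- toy_mixed_data(13, sigma = 0)
  f1 <- glmm_ml(d$y, d$X, d$group, sigma_zero = TRUE)
  f2 <- glmm_ml(c(d$y, d$y), rbind(d$X, d$X), c(d$group, d$group),
                sigma_zero = TRUE)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-7)
  expect_equal(f1$se / f2$se, rep(sqrt(2), 2), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("the fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- toy_mixed_data(42, G = 8, npg = 40)
  fit <- glmm_ml(d$y, d$X, d$group, nodes = 15)
  df <- data.frame(y = d$y, x = d$X[, 2], g = d$group)
  m <- lme4::glmer(y ~ x + (1 | g), data = df, family = binomial, nAGQ = 15)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(m)),
               tolerance = 1e-4)
  expect_equal(fit$random_effect_sd,
               sqrt(unname(unlist(lme4::VarCorr(m)))), tolerance = 1e-3)
  expect_equal(fit$log_marginal_likelihood, as.numeric(logLik(m)),
               tolerance = 1e-5)
})

test_that("a truly homogeneous dataset drives sigma to the boundary safely", {
  d <- toy_mixed_data(31, G = 6, npg = 40, sigma = 0)
  fit <- glmm_ml(d$y, d$X, d$group, nodes = 7)
  expect_lt(fit$random_effect_sd, 0.15)
  expect_true(is.finite(fit$log_marginal_likelihood))
  expect_true(fit$converged)
})

test_that("natural-scale back-transform inverts standardization exactly", {
  d <- toy_mixed_data(17, G = 6, npg = 40)
  x_raw <- 5 + 3 * d$X[, 2]
  s <- standardize_columns(cbind(x = x_raw))
  f_std <- glmm_ml(d$y, cbind("(intercept)" = 1, s$x), d$group, nodes = 7)
  f_raw <- glmm_ml(d$y, cbind("(intercept)" = 1, x = x_raw), d$group,
                   nodes = 7)
  nat <- coef_natural(f_std, s$center, s$scale)
  expect_equal(nat$estimate, unname(f_raw$coefficients), tolerance = 1e-4)
  expect_equal(nat$se, unname(f_raw$se), tolerance = 1e-3)
})
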