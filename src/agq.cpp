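#include <Rcpp.h>
using namespace Rcpp;

// Numerically safe log(1 + exp(x)).
static inline double log1pexp_d(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double plogis_d(double x) {
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Plain Bernoulli-logit log-likelihood (random-effect SD fixed at zero).
// Returns loglik and, if wanted, the gradient with respect to beta.
// [[Rcpp::export]]
List bern_loglik_cpp(NumericVector beta, NumericVector y, NumericMatrix X,
                     bool want_grad) {
  int n = y.size(), p = beta.size();
  double ll = 0.0;
  NumericVector grad(p);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * beta[j];
    ll += y[i] * eta - log1pexp_d(eta);
    if (want_grad) {
      double r = y[i] - plogis_d(eta);
      for (int j = 0; j < p; ++j) grad[j] += r * X(i, j);
    }
  }
  if (!std::isfinite(ll)) stop("non-finite linear predictor in log-likelihood");
  return List::create(_["loglik"] = ll, _["grad"] = grad,
                      _["modes"] = R_NilValue, _["newton_iter"] = 0);
}

// Marginal log-likelihood of the Bernoulli-logit model with one Gaussian
// random intercept per group, integrated out by adaptive Gauss-Hermite
// quadrature.  The integral factorizes over groups; each group's integrand
// is centred at its conditional mode (found by damped Newton) and scaled by
// the curvature there, so one node reproduces the Laplace approximation.
//
// The gradient is the posterior expectation of the complete-data score,
// evaluated under the same quadrature rule:
//   d/d beta_j : sum_i E[(y_i - p_i(b))] x_ij
//   d/d log(sigma): sum_g E[b_g^2 / sigma^2 - 1]
//
// group must be 0-based and dense in [0, ngroups).
// [[Rcpp::export]]
List agq_loglik_cpp(NumericVector beta, double log_sigma, NumericVector y,
                    NumericMatrix X, IntegerVector group, int ngroups,
                    NumericVector nodes, NumericVector wts, bool want_grad) {
  int n = y.size(), p = beta.size(), K = nodes.size();
  double sigma = std::exp(log_sigma);
  double inv_s2 = 1.0 / (sigma * sigma);
  if (!std::isfinite(sigma) || sigma <= 0.0)
    stop("random-effect sd must be positive and finite on this path");

  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    if (!std::isfinite(e)) stop("non-finite linear predictor");
    eta0[i] = e;
  }

  // Damped Newton for the conditional mode of each group's integrand.
  std::vector<double> b(ngroups, 0.0), S1(ngroups), S2(ngroups);
  int iter = 0;
  for (; iter < 100; ++iter) {
    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int g = group[i];
      double pi = plogis_d(eta0[i] + b[g]);
      S1[g] += y[i] - pi;
      S2[g] += pi * (1.0 - pi);
    }
    double maxstep = 0.0;
    for (int g = 0; g < ngroups; ++g) {
      double gr = S1[g] - b[g] * inv_s2;
      double he = S2[g] + inv_s2;
      double step = gr / he;
      if (step > 3.0) step = 3.0;
      if (step < -3.0) step = -3.0;
      b[g] += step;
      double as = std::fabs(step);
      if (as > maxstep) maxstep = as;
    }
    if (maxstep < 1e-11) break;
  }

  // Curvature (and hence scale) at the mode.
  std::fill(S2.begin(), S2.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    int g = group[i];
    double pi = plogis_d(eta0[i] + b[g]);
    S2[g] += pi * (1.0 - pi);
  }
  std::vector<double> tau(ngroups);
  for (int g = 0; g < ngroups; ++g) tau[g] = 1.0 / std::sqrt(S2[g] + inv_s2);

  // Log integrand at each shifted/scaled node: F(g,k) = log w_k + x_k^2 +
  // A_g(b_gk) - b_gk^2/(2 sigma^2), with A_g the group's Bernoulli loglik.
  NumericMatrix F(ngroups, K);
  std::vector<double> bk(ngroups), A(ngroups);
  const double SQRT2 = std::sqrt(2.0);
  for (int k = 0; k < K; ++k) {
    for (int g = 0; g < ngroups; ++g) {
      bk[g] = b[g] + SQRT2 * tau[g] * nodes[k];
      A[g] = 0.0;
    }
    for (int i = 0; i < n; ++i) {
      int g = group[i];
      double eta = eta0[i] + bk[g];
      A[g] += y[i] * eta - log1pexp_d(eta);
    }
    double lw = std::log(wts[k]) + nodes[k] * nodes[k];
    for (int g = 0; g < ngroups; ++g)
      F(g, k) = lw + A[g] - 0.5 * bk[g] * bk[g] * inv_s2;
  }

  double ll = 0.0;
  std::vector<double> lse(ngroups);
  for (int g = 0; g < ngroups; ++g) {
    double m = F(g, 0);
    for (int k = 1; k < K; ++k)
      if (F(g, k) > m) m = F(g, k);
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(F(g, k) - m);
    lse[g] = m + std::log(s);
    ll += lse[g] + std::log(SQRT2 * tau[g]) - std::log(sigma) -
          0.5 * std::log(2.0 * M_PI);
  }
  if (!std::isfinite(ll)) stop("non-finite marginal log-likelihood");

  NumericVector grad(p + 1);
  if (want_grad) {
    for (int k = 0; k < K; ++k) {
      for (int g = 0; g < ngroups; ++g)
        bk[g] = b[g] + SQRT2 * tau[g] * nodes[k];
      for (int i = 0; i < n; ++i) {
        int g = group[i];
        double w = std::exp(F(g, k) - lse[g]);
        double r = w * (y[i] - plogis_d(eta0[i] + bk[g]));
        for (int j = 0; j < p; ++j) grad[j] += r * X(i, j);
      }
      for (int g = 0; g < ngroups; ++g) {
        double w = std::exp(F(g, k) - lse[g]);
        grad[p] += w * (bk[g] * bk[g] * inv_s2 - 1.0);
      }
    }
  }

  return List::create(_["loglik"] = ll, _["grad"] = grad,
                      _["modes"] = NumericVector(b.begin(), b.end()),
                      _["newton_iter"] = iter + 1);
}
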