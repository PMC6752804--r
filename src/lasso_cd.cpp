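#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent path for L1-penalised logistic regression.
//
// X must already be standardised (zero mean, unit population sd per
// column; all-zero columns are allowed and stay at zero).  For each
// lambda the solver minimises
//   (1/n) * sum_i -loglik_i(b0 + x_i'beta) + lambda * sum_j |beta_j|
// with an unpenalised intercept, using an outer IRLS quadratic
// approximation and an inner cyclic coordinate descent with
// soft-thresholding and an active-set strategy (iterate on the nonzero
// set, then one full sweep to check the KKT conditions).  The path is
// warm-started along the descending lambda grid.  Working weights are
// clamped below at 1e-5.  A saturated fit (held-in deviance ~ 0,
// quasi-separation at tiny lambda) stops iterating and is flagged via
// `diverged`, as is any fit whose coefficients exceed `cap`.

static inline double soft(double num, double lam) {
  double a = std::fabs(num);
  if (a <= lam) return 0.0;
  return (num > 0.0 ? a - lam : lam - a);
}

// [[Rcpp::export]]
List lasso_logistic_path_cpp(NumericMatrix X, NumericVector y,
                             NumericVector lambdas, double tol,
                             int maxit_irls, int maxit_cd, double cap) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix beta_out(p, L);
  NumericVector b0_out(L);
  IntegerVector diverged(L);

  std::vector<double> beta(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double b0 = std::log(ybar / (1.0 - ybar));

  std::vector<double> w(n), r(n);
  std::vector<int> active;
  active.reserve(p);

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    bool flagged = false;

    for (int it = 0; it < maxit_irls; ++it) {
      // quadratic approximation at the current coefficients
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j)
          if (beta[j] != 0.0) e += X(i, j) * beta[j];
        double pr = 1.0 / (1.0 + std::exp(-e));
        double pc = std::min(std::max(pr, 1e-10), 1.0 - 1e-10);
        dev += -2.0 * (y[i] * std::log(pc) + (1.0 - y[i]) * std::log(1.0 - pc));
        double wi = pr * (1.0 - pr);
        if (wi < 1e-5) wi = 1e-5;
        w[i] = wi;
        // working residual z - eta with z = eta + (y - pr) / wi
        r[i] = (y[i] - pr) / wi;
      }
      if (dev / n < 1e-6) { flagged = true; break; }  // saturated fit

      double b0_old = b0;
      std::vector<double> beta_old(beta);

      auto update_one = [&](int j) -> double {
        double num = 0.0, den = 0.0;
        for (int i = 0; i < n; ++i) {
          const double xij = X(i, j);
          num += w[i] * xij * r[i];
          den += w[i] * xij * xij;
        }
        num = num / n + (den / n) * beta[j];
        den /= n;
        if (den <= 0.0) return 0.0;  // constant column
        const double bj = soft(num, lam) / den;
        const double d = bj - beta[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
          beta[j] = bj;
        }
        return std::fabs(d);
      };
      auto update_intercept = [&]() -> double {
        double sw = 0.0, swr = 0.0;
        for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * r[i]; }
        const double db0 = swr / sw;
        if (db0 != 0.0) {
          b0 += db0;
          for (int i = 0; i < n; ++i) r[i] -= db0;
        }
        return std::fabs(db0);
      };

      for (int cd = 0; cd < maxit_cd; ++cd) {
        // full sweep
        double dmax = update_intercept();
        for (int j = 0; j < p; ++j) dmax = std::max(dmax, update_one(j));
        if (dmax < tol) break;
        // iterate on the active set until stable
        active.clear();
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
        for (int as = 0; as < maxit_cd; ++as) {
          double amax = update_intercept();
          for (int j : active) amax = std::max(amax, update_one(j));
          if (amax < tol) break;
        }
      }

      double bmax = std::fabs(b0);
      double step = std::fabs(b0 - b0_old);
      for (int j = 0; j < p; ++j) {
        bmax = std::max(bmax, std::fabs(beta[j]));
        step = std::max(step, std::fabs(beta[j] - beta_old[j]));
      }
      if (bmax > cap) { flagged = true; break; }
      if (step < tol) break;
    }

    if (flagged) {
      if (b0 > cap) b0 = cap; else if (b0 < -cap) b0 = -cap;
      for (int j = 0; j < p; ++j) {
        if (beta[j] > cap) beta[j] = cap;
        else if (beta[j] < -cap) beta[j] = -cap;
      }
    }
    b0_out[l] = b0;
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    diverged[l] = flagged ? 1 : 0;
  }

  return List::create(_["b0"] = b0_out, _["beta"] = beta_out,
                      _["diverged"] = diverged);
}
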