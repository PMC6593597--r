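#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Objective (per-sample scale):
//   f(b0, beta) = -(1/n) * loglik(b0, beta)
//                 + lambda * [ alpha * sum_j w_j |beta_j|
//                            + (1 - alpha) * sum_j (w_j beta_j)^2 ]
// The ridge part carries w_j^2 because the weight enters inside the
// squared l2 norm of the Hadamard product w o beta.

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static inline double sigmoid(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Exact KKT residuals at (b0, beta).  Entry j (0-based) is the violation of
// the subgradient condition for beta_j; the returned vector has p + 1
// entries, the last being |mean(p_i - y_i)| (intercept stationarity).
// [[Rcpp::export(name = ".kkt_residuals_cpp")]]
NumericVector kkt_residuals_cpp(const NumericMatrix& X,
                                const NumericVector& y,
                                double b0,
                                const NumericVector& beta,
                                const NumericVector& w,
                                double alpha,
                                double lambda) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector res(p + 1);
  std::vector<double> d(n);
  double dsum = 0.0;
  {
    std::vector<double> eta(n, b0);
    const double* xp0 = X.begin();
    for (int j = 0; j < p; ++j)
      if (beta[j] != 0.0) {
        const double* xj = xp0 + (size_t)j * n;
        for (int i = 0; i < n; ++i) eta[i] += xj[i] * beta[j];
      }
    for (int i = 0; i < n; ++i) {
      d[i] = sigmoid(eta[i]) - y[i];
      dsum += d[i];
    }
  }
  const double* xp = X.begin();
  for (int j = 0; j < p; ++j) {
    const double* xj = xp + (size_t)j * n;
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += xj[i] * d[i];
    g /= n;
    double l1 = lambda * alpha * w[j];
    double l2 = 2.0 * lambda * (1.0 - alpha) * w[j] * w[j];
    if (beta[j] != 0.0) {
      double s = (beta[j] > 0.0) ? 1.0 : -1.0;
      res[j] = std::fabs(g + l2 * beta[j] + l1 * s);
    } else {
      res[j] = std::max(0.0, std::fabs(g) - l1);
    }
  }
  res[p] = std::fabs(dsum / n);
  return res;
}

// Weighted elastic-net logistic regression along a descending lambda path.
// Proximal Newton (IRLS quadratic + cyclic coordinate descent) restricted
// to an ever-active gene set, with full exact KKT sweeps adding violators,
// warm-started along the path.
// [[Rcpp::export(name = ".cd_logistic_path_cpp")]]
List cd_logistic_path(const NumericMatrix& X,
                      const NumericVector& y,
                      const NumericVector& w,
                      double alpha,
                      const NumericVector& lambdas,
                      double tol,
                      double kkt_tol,
                      int max_iter) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambdas.size();
  const double vmin = 1e-5;

  NumericMatrix betas(p, nlam);
  NumericVector intercepts(nlam);
  IntegerVector n_sweeps(nlam);
  LogicalVector conv(nlam);
  NumericVector kkt_max(nlam);

  std::vector<double> beta(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double b0 = std::log(ybar / (1.0 - ybar));

  std::vector<double> eta(n, b0), v(n), r(n), z(n), xv(p);
  std::vector<int> active;
  std::vector<char> in_active(p, 0);
  active.reserve(p);
  // unpenalized genes are always active
  for (int j = 0; j < p; ++j)
    if (w[j] == 0.0) { active.push_back(j); in_active[j] = 1; }

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambdas[l];
    int sweeps = 0;
    bool ok = false;
    double worst = R_PosInf;

    for (int screen = 0; screen < 1 + p && sweeps < max_iter; ++screen) {
      // proximal Newton on the current active set
      for (int outer = 0; outer < 100 && sweeps < max_iter; ++outer) {
        double vsum = 0.0, dirls = 0.0;
        for (int i = 0; i < n; ++i) {
          double pi = sigmoid(eta[i]);
          double vi = pi * (1.0 - pi);
          if (vi < vmin) vi = vmin;
          v[i] = vi;
          r[i] = (y[i] - pi) / vi;   // working residual z - eta
          z[i] = eta[i] + r[i];
          vsum += vi;
        }
        for (size_t a = 0; a < active.size(); ++a) {
          int j = active[a];
          const double* xj = X.begin() + (size_t)j * n;
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += v[i] * xj[i] * xj[i];
          xv[j] = s / n;
        }
        // coordinate descent on the quadratic
        for (int inner = 0; inner < 10000 && sweeps < max_iter; ++inner) {
          double dmax = 0.0;
          for (size_t a = 0; a < active.size(); ++a) {
            int j = active[a];
            const double* xj = X.begin() + (size_t)j * n;
            double rho = 0.0;
            for (int i = 0; i < n; ++i) rho += v[i] * xj[i] * r[i];
            rho = rho / n + xv[j] * beta[j];
            double denom = xv[j] + 2.0 * lam * (1.0 - alpha) * w[j] * w[j];
            double bj = soft_threshold(rho, lam * alpha * w[j]) / denom;
            double diff = bj - beta[j];
            if (diff != 0.0) {
              for (int i = 0; i < n; ++i) r[i] -= xj[i] * diff;
              beta[j] = bj;
              double ad = std::fabs(diff);
              if (ad > dmax) dmax = ad;
            }
          }
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += v[i] * r[i];
          double d0 = num / vsum;
          if (d0 != 0.0) {
            b0 += d0;
            for (int i = 0; i < n; ++i) r[i] -= d0;
            if (std::fabs(d0) > dmax) dmax = std::fabs(d0);
          }
          ++sweeps;
          if (dmax > dirls) dirls = dmax;
          if (dmax < tol) break;
        }
        // linear predictor after this Newton step
        for (int i = 0; i < n; ++i) eta[i] = z[i] - r[i];
        if (dirls < tol) break;   // quadratic no longer moves the iterate
      }

      // full exact KKT sweep; add violators to the active set
      std::vector<double> d(n);
      double dsum = 0.0;
      for (int i = 0; i < n; ++i) {
        d[i] = sigmoid(eta[i]) - y[i];
        dsum += d[i];
      }
      worst = std::fabs(dsum / n);
      bool added = false;
      for (int j = 0; j < p; ++j) {
        const double* xj = X.begin() + (size_t)j * n;
        double g = 0.0;
        for (int i = 0; i < n; ++i) g += xj[i] * d[i];
        g /= n;
        double l1 = lam * alpha * w[j];
        double viol;
        if (beta[j] != 0.0) {
          double s = (beta[j] > 0.0) ? 1.0 : -1.0;
          viol = std::fabs(g + 2.0 * lam * (1.0 - alpha) * w[j] * w[j] * beta[j]
                           + l1 * s);
        } else {
          viol = std::max(0.0, std::fabs(g) - l1);
        }
        if (viol > worst) worst = viol;
        if (!in_active[j] && viol >= kkt_tol) {
          active.push_back(j);
          in_active[j] = 1;
          added = true;
        }
      }
      if (worst < kkt_tol) { ok = true; break; }
      if (!added) {
        // active set is complete but the Newton loop stalled; keep iterating
        // unless the sweep budget is exhausted
        if (sweeps >= max_iter) break;
        continue;
      }
    }

    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    intercepts[l] = b0;
    n_sweeps[l] = sweeps;
    conv[l] = ok;
    kkt_max[l] = worst;
  }

  return List::create(_["beta"] = betas,
                      _["intercept"] = intercepts,
                      _["n_sweeps"] = n_sweeps,
                      _["converged"] = conv,
                      _["kkt_max"] = kkt_max);
}
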