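#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Stratified Cox partial likelihood with Breslow tie handling.
//
// All entry points expect the data pre-sorted by stratum and, within each
// stratum, by ascending follow-up time (the R wrappers take care of this).
// str_start / str_end are 0-based inclusive index ranges, one per stratum.

static const double ETA_CAP = 80.0;   // exp() overflow guard
static const double BETA_CAP = 30.0;  // monotone-likelihood runaway guard

// Per-observation score g_i = dl/deta_i and (diagonal) information
// h_i = -d2l/deta_i^2 of the Breslow partial log-likelihood, plus the
// log-likelihood itself. Risk-set sums are suffix sums over the sorted
// stratum; tied times share one risk set.
static void breslow_eta_derivs(const NumericVector &eta,
                               const NumericVector &time,
                               const NumericVector &status,
                               const IntegerVector &str_start,
                               const IntegerVector &str_end,
                               std::vector<double> &g,
                               std::vector<double> &h,
                               double &loglik) {
  loglik = 0.0;
  const int S = str_start.size();
  for (int s = 0; s < S; ++s) {
    const int a = str_start[s], b = str_end[s];
    const int m = b - a + 1;
    std::vector<double> ex(m);
    std::vector<double> suffix(m + 1, 0.0);
    for (int i = 0; i < m; ++i) {
      double e = eta[a + i];
      if (e > ETA_CAP) e = ETA_CAP;
      if (e < -ETA_CAP) e = -ETA_CAP;
      ex[i] = std::exp(e);
    }
    for (int i = m - 1; i >= 0; --i) suffix[i] = suffix[i + 1] + ex[i];
    double accA = 0.0, accB = 0.0;
    int i = 0;
    while (i < m) {
      int j = i, d = 0;
      while (j < m && time[a + j] == time[a + i]) {
        if (status[a + j] > 0) ++d;
        ++j;
      }
      if (d > 0) {
        const double R = suffix[i];
        accA += d / R;
        accB += d / (R * R);
        for (int k = i; k < j; ++k)
          if (status[a + k] > 0) loglik += eta[a + k];
        loglik -= d * std::log(R);
      }
      for (int k = i; k < j; ++k) {
        g[a + k] = status[a + k] - ex[k] * accA;
        double hk = ex[k] * accA - ex[k] * ex[k] * accB;
        h[a + k] = hk > 0.0 ? hk : 0.0;
      }
      i = j;
    }
  }
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One full or active-set coordinate-descent sweep over the weighted-lasso
// subproblem; returns the largest absolute coefficient change.
static double cd_sweep(const NumericMatrix &X, const std::vector<double> &w,
                       std::vector<double> &r, std::vector<double> &beta,
                       const std::vector<double> &v,
                       const NumericVector &penalty, double lam,
                       const std::vector<int> &idx) {
  const int n = X.nrow();
  double delta = 0.0;
  for (size_t jj = 0; jj < idx.size(); ++jj) {
    const int j = idx[jj];
    if (v[j] <= 1e-300) continue;
    double u = 0.0;
    for (int i = 0; i < n; ++i) u += w[i] * X(i, j) * r[i];
    u += v[j] * beta[j];
    double bnew = soft(u, lam * penalty[j]) / v[j];
    if (bnew > BETA_CAP) bnew = BETA_CAP;
    if (bnew < -BETA_CAP) bnew = -BETA_CAP;
    const double diff = bnew - beta[j];
    if (diff != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * diff;
      beta[j] = bnew;
      const double ad = std::fabs(diff);
      if (ad > delta) delta = ad;
    }
  }
  return delta;
}

// Penalized stratified Cox fit along a decreasing lambda sequence.
// Objective: -(1/n) * loglik(beta) + lambda * sum_j penalty[j] * |beta_j|.
// Outer IRLS (diagonal-Hessian working response) with an inner cyclic
// coordinate-descent weighted-lasso solve (active-set iterations between
// full sweeps); warm starts along the path. The path stops early once the
// number of nonzero penalized coefficients exceeds dfmax (the saturated
// regime); remaining columns repeat the last fitted solution and
// nlambda_fitted records how many grid points were genuinely solved.
// [[Rcpp::export]]
List cox_lasso_path_cpp(const NumericMatrix &X,
                        const NumericVector &time,
                        const NumericVector &status,
                        const IntegerVector &str_start,
                        const IntegerVector &str_end,
                        const NumericVector &penalty,
                        const NumericVector &lambda,
                        const NumericVector &beta_init,
                        double tol, int maxit, int dfmax) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix beta_out(p, L);
  NumericVector loglik_out(L);
  IntegerVector iters_out(L);

  std::vector<double> beta(p);
  for (int j = 0; j < p; ++j) beta[j] = beta_init[j];
  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
  }

  std::vector<double> g(n), h(n), w(n), z(n), r(n);
  std::vector<int> all_idx(p);
  for (int j = 0; j < p; ++j) all_idx[j] = j;
  if (dfmax <= 0) dfmax = p;

  int nfitted = 0;
  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    double ll = 0.0;
    int it = 0;
    double prev_outer = 1e-2;  // adaptive inner threshold seed
    for (; it < maxit; ++it) {
      breslow_eta_derivs(eta, time, status, str_start, str_end, g, h, ll);
      for (int i = 0; i < n; ++i) {
        w[i] = h[i] / n;
        if (h[i] > 1e-12) {
          z[i] = eta[i] + g[i] / h[i];
        } else {
          w[i] = 0.0;
          z[i] = eta[i];
        }
        r[i] = z[i] - eta[i];  // working residual at current beta
      }
      std::vector<double> v(p, 0.0);
      for (int j = 0; j < p; ++j) {
        double vj = 0.0;
        for (int i = 0; i < n; ++i) vj += w[i] * X(i, j) * X(i, j);
        v[j] = vj;
      }
      std::vector<double> beta_old(beta);
      // Solve the working weighted lasso only slightly tighter than the
      // current outer error: the outer IRLS converges linearly, so
      // over-solving the inner problem is wasted work. Full sweep, then
      // iterate the active set, until a full sweep moves nothing new.
      double inner_thr = prev_outer * 1e-2;
      if (inner_thr < tol) inner_thr = tol;
      for (int round = 0; round < 5; ++round) {
        double full_delta =
            cd_sweep(X, w, r, beta, v, penalty, lam, all_idx);
        if (full_delta < inner_thr) break;
        std::vector<int> active;
        for (int j = 0; j < p; ++j)
          if (beta[j] != 0.0 || penalty[j] == 0.0) active.push_back(j);
        for (int cycle = 0; cycle < 50; ++cycle) {
          if (cd_sweep(X, w, r, beta, v, penalty, lam, active) < inner_thr)
            break;
        }
      }
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
        eta[i] = e;
      }
      double outer_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double d = std::fabs(beta[j] - beta_old[j]);
        if (d > outer_delta) outer_delta = d;
      }
      prev_outer = outer_delta;
      if (outer_delta < tol) {
        ++it;
        break;
      }
    }
    breslow_eta_derivs(eta, time, status, str_start, str_end, g, h, ll);
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    loglik_out[l] = ll;
    iters_out[l] = it;
    nfitted = l + 1;
    int df = 0;
    for (int j = 0; j < p; ++j)
      if (penalty[j] > 0.0 && beta[j] != 0.0) ++df;
    // saturation stops: too many active coefficients, or a vanishing
    // likelihood gain from further relaxation of the penalty
    bool saturated = df > dfmax;
    if (l > 0 && !saturated &&
        std::fabs(ll - loglik_out[l - 1]) < 1e-5 * std::fabs(ll))
      saturated = true;
    if (saturated) {
      for (int l2 = l + 1; l2 < L; ++l2) {
        for (int j = 0; j < p; ++j) beta_out(j, l2) = beta[j];
        loglik_out[l2] = ll;
        iters_out[l2] = 0;
      }
      break;
    }
  }
  return List::create(_["beta"] = beta_out, _["loglik"] = loglik_out,
                      _["iters"] = iters_out,
                      _["nlambda_fitted"] = nfitted);
}

// Log-likelihood and gradient of (1/n) * loglik with respect to beta,
// at a fixed coefficient vector (used for lambda_max, KKT checks, CV).
// [[Rcpp::export]]
List cox_loglik_grad_cpp(const NumericMatrix &X,
                         const NumericVector &time,
                         const NumericVector &status,
                         const IntegerVector &str_start,
                         const IntegerVector &str_end,
                         const NumericVector &beta) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
  }
  std::vector<double> g(n), h(n);
  double ll = 0.0;
  breslow_eta_derivs(eta, time, status, str_start, str_end, g, h, ll);
  NumericVector grad(p);
  for (int j = 0; j < p; ++j) {
    double gj = 0.0;
    for (int i = 0; i < n; ++i) gj += X(i, j) * g[i];
    grad[j] = gj / n;
  }
  return List::create(_["loglik"] = ll, _["grad"] = grad);
}
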