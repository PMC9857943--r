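#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// SMO solver for the per-sample-weighted soft-margin SVM dual:
//   max  sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij
//   s.t. sum(y * alpha) = 0,  0 <= alpha_i <= ub_i
// Second-order (quadratic-gain) working-set selection on the maximal
// violating pair; deterministic for a fixed input order. K must be
// symmetric (columns are used as rows). An optional feasible alpha0
// warm-starts the solve, e.g. along an increasing-C path.
//
// Internally minimises f(a) = 0.5 a'Qa - e'a with Q_ij = y_i y_j K_ij.
// G_i = df/da_i; for the decision value u(x) = sum_j a_j y_j K(x_j, x),
// -y_i G_i = y_i - u(x_i), which yields both the stopping criterion and
// the feasible bias interval.

// [[Rcpp::export]]
List smo_solve(const NumericMatrix& K, const NumericVector& y,
               const NumericVector& ub, double tol, int max_iter,
               Nullable<NumericVector> alpha0 = R_NilValue) {
  const int n = K.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  const double* Kp = K.begin();
  std::vector<double> alpha(n, 0.0), G(n, -1.0), diag(n);
  for (int t = 0; t < n; ++t) diag[t] = Kp[(R_xlen_t)t * n + t];

  if (alpha0.isNotNull()) {
    NumericVector a0(alpha0.get());
    bool any = false;
    for (int t = 0; t < n; ++t) {
      alpha[t] = std::min(std::max(a0[t], 0.0), ub[t]);
      if (alpha[t] != 0.0) any = true;
    }
    if (any) {  // G = Q alpha - e, accumulated column-wise
      for (int s = 0; s < n; ++s) {
        if (alpha[s] == 0.0) continue;
        const double* Ks = Kp + (R_xlen_t)s * n;
        double c = y[s] * alpha[s];
        for (int t = 0; t < n; ++t) G[t] += y[t] * c * Ks[t];
      }
    }
  }

  int iter = 0;
  double gmax = inf, gmin = -inf;
  while (iter < max_iter) {
    int i = -1;
    gmax = -inf;
    gmin = inf;
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] > 0) ? (alpha[t] < ub[t]) : (alpha[t] > 0);
      if (in_up) {
        double v = -y[t] * G[t];
        if (v > gmax) { gmax = v; i = t; }
      }
    }
    int j = -1;
    double best = 0.0;  // require strictly negative quadratic-gain value
    const double* Ki = (i >= 0) ? Kp + (R_xlen_t)i * n : nullptr;
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < ub[t]);
      if (in_low) {
        double v = -y[t] * G[t];
        if (v < gmin) gmin = v;
        double b = gmax - v;  // violation of pair (i, t)
        if (i >= 0 && b > 0) {
          double a = diag[i] + diag[t] - 2.0 * Ki[t];
          if (a <= 0) a = 1e-12;  // numerically semi-definite direction
          double val = -(b * b) / a;
          if (val < best) { best = val; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    // step along u = e_i * y_i - e_j * y_j (preserves sum(y * alpha))
    const double* Kj = Kp + (R_xlen_t)j * n;
    double a = diag[i] + diag[j] - 2.0 * Ki[j];
    if (a <= 0) a = 1e-12;
    double g = y[i] * G[i] - y[j] * G[j];  // directional derivative (< 0)
    double d = -g / a;
    // box clipping: alpha_i + y_i d in [0, ub_i], alpha_j - y_j d in [0, ub_j]
    double dmax_i = (y[i] > 0) ? (ub[i] - alpha[i]) : alpha[i];
    double dmax_j = (y[j] > 0) ? alpha[j] : (ub[j] - alpha[j]);
    if (d > dmax_i) d = dmax_i;
    if (d > dmax_j) d = dmax_j;

    alpha[i] += y[i] * d;
    alpha[j] -= y[j] * d;
    // clamp tiny numerical overshoot
    if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > ub[i]) alpha[i] = ub[i];
    if (alpha[j] < 0) alpha[j] = 0; else if (alpha[j] > ub[j]) alpha[j] = ub[j];

    for (int t = 0; t < n; ++t)
      G[t] += y[t] * d * (Ki[t] - Kj[t]);
    ++iter;
  }

  // dual objective: sum(alpha) - 0.5 sum a_i a_j y_i y_j K_ij
  //               = 0.5 * (e'a - a'G) since a'G = a'Qa - e'a
  double ea = 0.0, aG = 0.0;
  for (int t = 0; t < n; ++t) { ea += alpha[t]; aG += alpha[t] * G[t]; }
  double objective = 0.5 * (ea - aG);

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["objective"] = objective,
    _["iterations"] = iter,
    _["converged"] = (iter < max_iter),
    _["gap"] = gmax - gmin,
    _["b_interval"] = NumericVector::create((gmax + gmin) / 2.0, gmin, gmax));
}
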