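#include <Rcpp.h>
using namespace Rcpp;

// Weighted LASSO by cyclic coordinate descent with an active-set strategy.
//
// Minimises, for each penalty value alpha in `alpha_path` (warm-started in
// the given order, so the caller should pass a decreasing path):
//
//   Cost(b0, b) = sum_i w_i (y_i - b0 - sum_j b_j x_ij)^2 + alpha sum_j |b_j|
//
// The intercept b0 is unpenalised.  Features are used on their native scale
// (no internal standardisation).  Convergence: the largest per-coordinate
// objective decrease in a sweep, max_j xwx_j * (delta b_j)^2, falls below
// tol times the weighted null deviance sum_i w_i (y_i - ybar_w)^2 (the
// criterion used by standard coordinate-descent LASSO solvers; it remains
// well behaved when p > n and the minimiser is not unique), or maxit sweeps.
//
// Returns intercepts, a dense coefficient matrix (p x n_alpha), the number
// of sweeps used and a convergence flag per path point.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_lasso_path")]]
List cd_lasso_path(NumericMatrix X, NumericVector y, NumericVector w,
                   NumericVector alpha_path, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), na = alpha_path.size();

  std::vector<double> xwx(p);        // sum_i w_i x_ij^2
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double *xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
    xwx[j] = s;
  }
  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];

  std::vector<double> b(p, 0.0);
  double b0 = 0.0;
  {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * y[i];
    b0 = s / sw;
  }
  std::vector<double> r(n);          // residual y - b0 - X b
  double dev_null = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = y[i] - b0;
    dev_null += w[i] * r[i] * r[i];
  }
  if (dev_null <= 0.0) dev_null = 1.0;  // constant response: any tol works
  const double thr_conv = tol * dev_null;

  NumericMatrix beta_out(p, na);
  NumericVector b0_out(na);
  IntegerVector iter_out(na);
  LogicalVector conv_out(na);

  std::vector<int> active;
  std::vector<bool> is_active(p, false);

  for (int a = 0; a < na; ++a) {
    const double thr = alpha_path[a] / 2.0;
    int it = 0;
    bool converged = false;

    while (it < maxit) {
      // full sweep over all coordinates; rebuild active set
      ++it;
      double dmax = 0.0;
      active.clear();
      std::fill(is_active.begin(), is_active.end(), false);
      for (int j = 0; j < p; ++j) {
        if (xwx[j] <= 0.0) continue;   // zero-variance/all-zero feature
        const double *xj = &X(0, j);
        double z = 0.0;
        for (int i = 0; i < n; ++i) z += w[i] * xj[i] * r[i];
        z += xwx[j] * b[j];
        double bj = soft(z, thr) / xwx[j];
        if (bj != b[j]) {
          double d = bj - b[j];
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
          double dd = xwx[j] * d * d;
          if (dd > dmax) dmax = dd;
          b[j] = bj;
        }
        if (b[j] != 0.0) { active.push_back(j); is_active[j] = true; }
      }
      {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * r[i];
        double d = s / sw;
        double dd = sw * d * d;
        if (dd > dmax) dmax = dd;
        b0 += d;
        for (int i = 0; i < n; ++i) r[i] -= d;
      }
      if (dmax < thr_conv) { converged = true; break; }

      // inner loop on the active set until stable
      while (it < maxit) {
        ++it;
        double dmax2 = 0.0;
        for (size_t k = 0; k < active.size(); ++k) {
          int j = active[k];
          const double *xj = &X(0, j);
          double z = 0.0;
          for (int i = 0; i < n; ++i) z += w[i] * xj[i] * r[i];
          z += xwx[j] * b[j];
          double bj = soft(z, thr) / xwx[j];
          if (bj != b[j]) {
            double d = bj - b[j];
            for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
            double dd = xwx[j] * d * d;
            if (dd > dmax2) dmax2 = dd;
            b[j] = bj;
          }
        }
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * r[i];
        double d = s / sw;
        double dd = sw * d * d;
        if (dd > dmax2) dmax2 = dd;
        b0 += d;
        for (int i = 0; i < n; ++i) r[i] -= d;
        if (dmax2 < thr_conv) break;
      }
      // loop back to a full sweep to verify KKT over excluded coordinates
    }

    for (int j = 0; j < p; ++j) beta_out(j, a) = b[j];
    b0_out[a] = b0;
    iter_out[a] = it;
    conv_out[a] = converged;
  }

  return List::create(_["beta"] = beta_out, _["b0"] = b0_out,
                      _["iter"] = iter_out, _["converged"] = conv_out);
}
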