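#include <Rcpp.h>
using namespace Rcpp;

// Gauss-Seidel iteration on data for the weighted SNP-BLUP mixed model
// equations
//   [ 1'W1   1'WZ        ] [mu]   [1'Wy]
//   [ Z'W1   Z'WZ + kI   ] [g ] = [Z'Wy]
// with W = diag(w), w_i the record weight (edc_i / sigma2_e) and
// k = n_snp / sigma2_a the shrinkage on each SNP effect. One sweep updates
// the general mean first, then every SNP effect in map order, maintaining
// the residual vector e = y - mu - Z g incrementally after every
// single-effect update. Columns flagged inactive (zero variance) keep a
// zero effect. Convergence: relative L2 change of the full solution vector
// across one sweep below tol.
// [[Rcpp::export]]
List snpblup_gs_cpp(const NumericMatrix& Z, const NumericVector& y,
                    const NumericVector& w, double shrink, double tol,
                    int max_iter, const LogicalVector& active) {
  const int n = Z.nrow();
  const int m = Z.ncol();
  std::vector<double> e(n), diag(m);
  double mu = 0.0;
  std::vector<double> g(m, 0.0);
  double sw = 0.0;
  for (int i = 0; i < n; ++i) { e[i] = y[i]; sw += w[i]; }
  for (int j = 0; j < m; ++j) {
    double d = 0.0;
    for (int i = 0; i < n; ++i) d += w[i] * Z(i, j) * Z(i, j);
    diag[j] = d + shrink;
  }
  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * (e[i] + mu);
    double mu_new = (sw > 0.0) ? num / sw : 0.0;
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    double delta2 = dmu * dmu;
    double size2 = mu_new * mu_new;
    mu = mu_new;
    for (int j = 0; j < m; ++j) {
      if (!active[j]) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += w[i] * Z(i, j) * e[i];
      rhs += (diag[j] - shrink) * g[j];
      double gj = rhs / diag[j];
      double dg = gj - g[j];
      if (dg != 0.0) {
        for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * dg;
      }
      delta2 += dg * dg;
      size2 += gj * gj;
      g[j] = gj;
    }
    if (std::sqrt(delta2) <= tol * (std::sqrt(size2) + 1e-300)) {
      converged = true;
      break;
    }
  }
  return List::create(_["mu"] = mu, _["g"] = NumericVector(g.begin(), g.end()),
                      _["e"] = NumericVector(e.begin(), e.end()),
                      _["converged"] = converged, _["n_iter"] = iter);
}
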