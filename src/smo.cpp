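#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// SMO solver for the soft-margin SVM dual with per-sample box constraints:
//
//   min_beta  1/2 beta' Q beta - e' beta
//   s.t.      y' beta = 0,  0 <= beta_n <= U_n,   Q_nm = y_n y_m K_nm.
//
// With U_n = C * c_n this is exactly the weighted-hinge-loss SVM dual after
// the change of variables beta_n = alpha_n * c_n.  Working-set selection is
// the maximal violating pair; convergence when the pairwise KKT violation
// m(beta) - M(beta) drops below tol.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, NumericVector U,
               double tol, int max_iter) {
  const int N = K.nrow();
  std::vector<double> beta(N, 0.0);
  std::vector<double> G(N, -1.0);  // gradient of the min-form objective
  const double bnd_eps = 1e-12;

  double gmax = 0.0, gmin = 0.0;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // i maximizes -y*G over I_up, j minimizes -y*G over I_low
    int i = -1, j = -1;
    gmax = -INFINITY;
    gmin = INFINITY;
    for (int n = 0; n < N; ++n) {
      const double v = -y[n] * G[n];
      const bool at_lo = beta[n] <= bnd_eps;
      const bool at_up = beta[n] >= U[n] - bnd_eps;
      const bool in_up  = (y[n] > 0) ? !at_up : !at_lo;
      const bool in_low = (y[n] > 0) ? !at_lo : !at_up;
      if (in_up && v > gmax) { gmax = v; i = n; }
      if (in_low && v < gmin) { gmin = v; j = n; }
    }
    if (i < 0 || j < 0 || gmax - gmin <= tol) { converged = true; break; }

    // analytic step along (y_i e_i - y_j e_j), curvature a = Kii+Kjj-2Kij
    double a = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (a <= 1e-12) a = 1e-12;
    double t = (gmax - gmin) / a;

    // box caps keeping beta_i + y_i t in [0,U_i] and beta_j - y_j t in [0,U_j]
    double cap_i = (y[i] > 0) ? (U[i] - beta[i]) : beta[i];
    double cap_j = (y[j] > 0) ? beta[j] : (U[j] - beta[j]);
    if (t > cap_i) t = cap_i;
    if (t > cap_j) t = cap_j;
    if (t <= 0) { converged = true; break; }  // numerically stuck at a bound

    beta[i] += y[i] * t;
    beta[j] -= y[j] * t;
    if (beta[i] < 0) beta[i] = 0; else if (beta[i] > U[i]) beta[i] = U[i];
    if (beta[j] < 0) beta[j] = 0; else if (beta[j] > U[j]) beta[j] = U[j];
    for (int n = 0; n < N; ++n) G[n] += t * y[n] * (K(n, i) - K(n, j));
  }

  // bias: average of -y*G over free vectors, else midpoint of [gmax, gmin]
  double bsum = 0.0;
  int nfree = 0;
  for (int n = 0; n < N; ++n) {
    const double rel = std::max(1.0, U[n]);
    if (beta[n] > 1e-8 * rel && beta[n] < U[n] - 1e-8 * rel) {
      bsum += -y[n] * G[n];
      ++nfree;
    }
  }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else if (std::isfinite(gmax) && std::isfinite(gmin)) b = 0.5 * (gmax + gmin);
  else if (std::isfinite(gmax)) b = gmax;
  else if (std::isfinite(gmin)) b = gmin;
  else b = 0.0;

  // dual objective in maximization form: e'beta - 1/2 beta'Q beta
  double obj = 0.0;
  for (int n = 0; n < N; ++n) obj += beta[n] - 0.5 * beta[n] * (G[n] + 1.0);

  double viol = (std::isfinite(gmax) && std::isfinite(gmin)) ? gmax - gmin : 0.0;
  if (viol < 0) viol = 0.0;

  return List::create(
    _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["bias"] = b,
    _["objective"] = obj,
    _["iterations"] = iter,
    _["converged"] = converged,
    _["kkt_violation"] = viol);
}
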