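// Dense linear algebra for the spatio-temporal Gaussian layer.
//
// The marginal covariance of the transition residuals is
//   Sigma = sigma2_z * Omega(phi, rho, delta) + sigma2_e * I
// with the double-exponential non-separable correlation
//   Omega(ds, dt) = exp(-ds/phi - dt/rho - delta * (ds/phi) * (dt/rho)).
// Everything is evaluated through Cholesky factorisations; no explicit
// inverses.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat st_corr(const mat& ds, const mat& dt, double phi, double rho,
                   double delta) {
  mat e = ds / phi + dt / rho + (delta / (phi * rho)) * (ds % dt);
  return exp(-e);
}

// [[Rcpp::export(name = ".st_corr_cpp")]]
arma::mat st_corr_cpp(const arma::mat& ds, const arma::mat& dt, double phi,
                      double rho, double delta) {
  return st_corr(ds, dt, phi, rho, delta);
}

// log N(r; 0, s2z * Omega + s2e * I). Returns -Inf coded as NA if the
// factorisation fails (caller decides how to report).
// [[Rcpp::export(name = ".mvn_loglik_cpp")]]
double mvn_loglik_cpp(const arma::vec& r, const arma::mat& ds,
                      const arma::mat& dt, double phi, double rho,
                      double delta, double s2z, double s2e) {
  const uword n = r.n_elem;
  mat S = s2z * st_corr(ds, dt, phi, rho, delta);
  S.diag() += s2e;
  mat L;
  if (!chol(L, S, "lower")) return NA_REAL;
  vec u = solve(trimatl(L), r);
  double logdet = 2.0 * accu(log(L.diag()));
  return -0.5 * (n * std::log(2.0 * M_PI) + logdet + dot(u, u));
}

// Same likelihood for several residual vectors (columns of R) under one
// parameter value: one factorisation, many quadratic forms. Used for the
// candidate-grid deviance pass.
// [[Rcpp::export(name = ".mvn_loglik_multi_cpp")]]
arma::vec mvn_loglik_multi_cpp(const arma::mat& R, const arma::mat& ds,
                               const arma::mat& dt, double phi, double rho,
                               double delta, double s2z, double s2e) {
  const uword n = R.n_rows;
  mat S = s2z * st_corr(ds, dt, phi, rho, delta);
  S.diag() += s2e;
  mat L;
  vec out(R.n_cols);
  if (!chol(L, S, "lower")) { out.fill(NA_REAL); return out; }
  mat U = solve(trimatl(L), R);
  double base = n * std::log(2.0 * M_PI) + 2.0 * accu(log(L.diag()));
  for (uword j = 0; j < R.n_cols; ++j) {
    out(j) = -0.5 * (base + dot(U.col(j), U.col(j)));
  }
  return out;
}

// Collapsed-sampler ingredients: with Sigma = s2 * V, V = kappa * Omega +
// (1 - kappa) * I (unit diagonal), the total variance s2 integrates out of
// the posterior analytically under the inverse-gamma priors. Returns
// (logdet V, r' V^{-1} r), or NAs if the factorisation fails. `dsdt` is the
// precomputed elementwise product ds % dt; only the lower triangle is
// exponentiated (the hot loop of the sampler).
// [[Rcpp::export(name = ".collapsed_parts_cpp")]]
arma::vec collapsed_parts_cpp(const arma::vec& r, const arma::mat& ds,
                              const arma::mat& dt, const arma::mat& dsdt,
                              double phi, double rho, double delta,
                              double kappa) {
  const uword n = r.n_elem;
  const double a1 = 1.0 / phi, a2 = 1.0 / rho, a3 = delta / (phi * rho);
  mat V(n, n);
  for (uword j = 0; j < n; ++j) {
    V(j, j) = 1.0;  // kappa + (1 - kappa)
    for (uword i = j + 1; i < n; ++i) {
      V(i, j) = kappa *
        std::exp(-(a1 * ds(i, j) + a2 * dt(i, j) + a3 * dsdt(i, j)));
    }
  }
  mat L;
  vec out(2);
  if (!chol(L, symmatl(V), "lower")) { out.fill(NA_REAL); return out; }
  vec u = solve(trimatl(L), r);
  out(0) = 2.0 * accu(log(L.diag()));
  out(1) = dot(u, u);
  return out;
}

// Fast path for the common survey layout: points form a complete stops x
// months grid, so the correlation matrix is block-Toeplitz in time and only
// one small spatial matrix per distinct temporal lag needs exponentiating.
// `r` must be ordered month-major (stop index fastest); `ds_stop` is the
// stop-distance matrix and `months` the ordered month values.
// [[Rcpp::export(name = ".collapsed_parts_grid_cpp")]]
arma::vec collapsed_parts_grid_cpp(const arma::vec& r,
                                   const arma::mat& ds_stop,
                                   const arma::vec& months, double phi,
                                   double rho, double delta, double kappa) {
  const uword ns = ds_stop.n_rows, nt = months.n_elem, n = ns * nt;
  const double a1 = 1.0 / phi, a2 = 1.0 / rho, a3 = delta / (phi * rho);
  // distinct lags and one spatial block per lag
  std::map<double, mat> lag_block;
  mat V(n, n);
  for (uword tj = 0; tj < nt; ++tj) {
    for (uword ti = tj; ti < nt; ++ti) {
      double lag = std::abs(months(ti) - months(tj));
      auto it = lag_block.find(lag);
      if (it == lag_block.end()) {
        mat E = kappa * exp(-(a2 * lag) - (a1 + a3 * lag) * ds_stop);
        if (lag == 0.0) E.diag().fill(1.0);  // kappa + (1 - kappa)
        it = lag_block.emplace(lag, std::move(E)).first;
      }
      V.submat(ti * ns, tj * ns, (ti + 1) * ns - 1, (tj + 1) * ns - 1) =
        it->second;
    }
  }
  mat L;
  vec out(2);
  if (!chol(L, symmatl(V), "lower")) { out.fill(NA_REAL); return out; }
  vec u = solve(trimatl(L), r);
  out(0) = 2.0 * accu(log(L.diag()));
  out(1) = dot(u, u);
  return out;
}

// Simple kriging: prediction c' C^{-1} z and variance s2z - c' C^{-1} c for
// each target, where C = s2z * Omega_dd + s2e * I among the data points and
// c the s2z-scaled cross-correlations to the target.
// [[Rcpp::export(name = ".simple_krige_cpp")]]
Rcpp::List simple_krige_cpp(const arma::vec& z, const arma::mat& ds,
                            const arma::mat& dt, const arma::mat& ds_cross,
                            const arma::mat& dt_cross, double phi, double rho,
                            double delta, double s2z, double s2e) {
  mat C = s2z * st_corr(ds, dt, phi, rho, delta);
  C.diag() += s2e;
  mat L;
  if (!chol(L, C, "lower")) {
    Rcpp::stop("kriging system is numerically singular (min diag of failed factor reported upstream)");
  }
  // cross-covariances: rows = data points, cols = targets
  mat Ccross = s2z * st_corr(ds_cross, dt_cross, phi, rho, delta);
  mat V = solve(trimatl(L), Ccross);
  vec u = solve(trimatl(L), z);
  vec pred = V.t() * u;
  vec kvar = s2z - sum(V % V, 0).t();
  // clamp tiny negatives from roundoff
  kvar.transform([](double v) { return v < 0 && v > -1e-10 ? 0.0 : v; });
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("var") = kvar);
}
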