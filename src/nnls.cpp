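#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set NNLS on the normal equations:
//   min ||A x - b||  s.t. x >= 0,
// given AtA = A'A and Atb = A'b. Intended for small k (few components)
// and many right-hand sides, as in alternating least squares sweeps.
// Rank-deficient passive-set solves fall back to a tiny ridge
// (1e-10 * mean diagonal); the caller is told how often via n_ridge.
static vec nnls_one(const mat& AtA, const vec& Atb, int& n_ridge) {
  const uword k = AtA.n_rows;
  vec x(k, fill::zeros);
  uvec passive(k, fill::zeros);            // 0/1 membership
  const double tol = 10.0 * datum::eps * std::max(1.0, abs(Atb).max());
  const uword max_outer = 3 * k + 10;

  vec w = Atb;                             // gradient at x = 0
  for (uword outer = 0; outer < max_outer; ++outer) {
    // most positive gradient among the active (zero) set
    double wmax = -datum::inf;
    uword jmax = k;
    for (uword j = 0; j < k; ++j) {
      if (!passive(j) && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (jmax == k || wmax <= tol) break;   // KKT satisfied
    passive(jmax) = 1;

    for (;;) {
      uvec P = find(passive == 1);
      mat App = AtA.submat(P, P);
      vec bp = Atb.elem(P);
      vec z;
      bool ok = solve(z, App, bp, solve_opts::no_approx);
      if (!ok || !z.is_finite()) {
        double ridge = 1e-10 * (trace(App) / App.n_rows + 1.0);
        mat Ar = App + ridge * eye<mat>(App.n_rows, App.n_rows);
        if (!solve(z, Ar, bp) || !z.is_finite()) z.zeros(P.n_elem);
        ++n_ridge;
      }
      if (z.min() > tol) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // step toward z until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword i = 0; i < P.n_elem; ++i) {
        if (z(i) <= tol) {
          double xi = x(P(i));
          double d = xi - z(i);
          if (d > 0) alpha = std::min(alpha, xi / d);
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword i = 0; i < P.n_elem; ++i)
        x(P(i)) += alpha * (z(i) - x(P(i)));
      for (uword i = 0; i < P.n_elem; ++i)
        if (x(P(i)) <= tol) { x(P(i)) = 0.0; passive(P(i)) = 0; }
      if (!any(passive)) { x.zeros(); break; }
    }
    w = Atb - AtA * x;
  }
  return x;
}

// Solve min ||A X - B||_F s.t. X >= 0 columnwise, with AtA = A'A (k x k)
// and AtB = A'B (k x nrhs). Returns k x nrhs solution and ridge-fallback
// count.
// [[Rcpp::export(name = ".nnlsNormal")]]
Rcpp::List nnls_normal(const arma::mat& AtA, const arma::mat& AtB) {
  const uword nrhs = AtB.n_cols;
  mat X(AtA.n_rows, nrhs);
  int n_ridge = 0;
  for (uword r = 0; r < nrhs; ++r)
    X.col(r) = nnls_one(AtA, AtB.col(r), n_ridge);
  return Rcpp::List::create(Rcpp::Named("X") = X,
                            Rcpp::Named("nRidge") = n_ridge);
}
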