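#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares for one right-hand side.
// Terminates at the KKT point; the dual tolerance is scaled by the magnitude
// of the initial gradient so the penalty-row augmentation (values ~200) does
// not swamp an absolute cutoff.
static vec nnls_one(const mat& A, const vec& b, double tol) {
  const uword m = A.n_cols;
  vec x(m, fill::zeros);
  uvec passive(m, fill::zeros);
  vec w = A.t() * b;
  double scale = std::max(1.0, arma::abs(w).max());
  double tol_w = tol * scale;

  const uword max_outer = 3 * m + 30;
  for (uword it = 0; it < max_outer; ++it) {
    sword jmax = -1;
    double wmax = tol_w;
    for (uword j = 0; j < m; ++j) {
      if (!passive(j) && w(j) > wmax) { wmax = w(j); jmax = (sword) j; }
    }
    if (jmax < 0) break;
    passive((uword) jmax) = 1;

    for (uword inner = 0; inner <= m; ++inner) {
      uvec P = find(passive == 1);
      mat AP = A.cols(P);
      vec sP;
      bool ok = solve(sP, AP, b, solve_opts::fast + solve_opts::no_approx);
      if (!ok) sP = pinv(AP) * b;

      if (sP.n_elem > 0 && sP.min() > 0.0) {
        x.zeros();
        x(P) = sP;
        break;
      }
      double alpha = datum::inf;
      for (uword t = 0; t < P.n_elem; ++t) {
        if (sP(t) <= 0.0) {
          double xi = x(P(t));
          double denom = xi - sP(t);
          if (denom > 0) {
            double a = xi / denom;
            if (a < alpha) alpha = a;
          }
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword t = 0; t < P.n_elem; ++t)
        x(P(t)) += alpha * (sP(t) - x(P(t)));
      for (uword t = 0; t < P.n_elem; ++t) {
        if (x(P(t)) <= tol) { passive(P(t)) = 0; x(P(t)) = 0.0; }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

//' Solve min ||A x_j - B_j||^2 s.t. x_j >= 0 for every column j of B.
//'
//' @param A design matrix (rows = equations, cols = variables)
//' @param B matrix of right-hand sides, one per column
//' @param tol active-set tolerance
//' @return matrix of non-negative solutions, one column per right-hand side
// [[Rcpp::export(name = ".nnls_multi")]]
arma::mat nnls_multi(const arma::mat& A, const arma::mat& B, double tol = 1e-10) {
  mat X(A.n_cols, B.n_cols, fill::zeros);
  for (uword j = 0; j < B.n_cols; ++j) {
    X.col(j) = nnls_one(A, B.col(j), tol);
  }
  return X;
}
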