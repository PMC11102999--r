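// Graphical lasso solved by block coordinate descent (lasso regressions on
// the current covariance estimate), with warm starts along a descending
// penalty path.  The diagonal is not penalised, matching the convention of
// EBIC-based network estimation in psychometrics.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// One glasso fit at penalty lam, warm-started from (W, B).  B stores the
// lasso coefficients of each column's regression.  Returns false if the
// fit failed to produce finite results.
static bool glasso_one(const mat& S, double lam, mat& W, mat& B,
                       mat& Theta, int maxit, double tol) {
  int p = S.n_rows;
  double thr = tol * mean(mean(abs(S - diagmat(S.diag())))); // avg |offdiag|
  if (thr <= 0) thr = tol;

  for (int it = 0; it < maxit; it++) {
    double dmax = 0.0;
    for (int j = 0; j < p; j++) {
      // coordinate descent for beta on W11
      for (int inner = 0; inner < maxit; inner++) {
        double bmax = 0.0;
        for (int k = 0; k < p; k++) {
          if (k == j) continue;
          double grad = S(k, j);
          for (int l = 0; l < p; l++) {
            if (l == j || l == k) continue;
            grad -= W(k, l) * B(l, j);
          }
          double bnew = soft(grad, lam) / W(k, k);
          double diff = std::fabs(bnew - B(k, j));
          if (diff > bmax) bmax = diff;
          B(k, j) = bnew;
        }
        if (bmax < thr * 0.1) break;
      }
      // w12 = W11 * beta
      for (int k = 0; k < p; k++) {
        if (k == j) continue;
        double wkj = 0.0;
        for (int l = 0; l < p; l++) {
          if (l == j) continue;
          wkj += W(k, l) * B(l, j);
        }
        double diff = std::fabs(wkj - W(k, j));
        if (diff > dmax) dmax = diff;
        W(k, j) = wkj;
        W(j, k) = wkj;
      }
    }
    if (dmax < thr) break;
  }

  // recover the precision matrix from the final regressions
  for (int j = 0; j < p; j++) {
    double denom = W(j, j);
    for (int l = 0; l < p; l++) {
      if (l == j) continue;
      denom -= W(l, j) * B(l, j);
    }
    if (!(denom > 0) || !std::isfinite(denom)) return false;
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (int l = 0; l < p; l++) {
      if (l == j) continue;
      Theta(l, j) = -B(l, j) * tjj;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());
  return Theta.is_finite();
}

// [[Rcpp::export]]
Rcpp::List cpp_glasso_path(const arma::mat& S, const arma::vec& lambdas,
                           int maxit, double tol) {
  int p = S.n_rows, nl = lambdas.n_elem;
  // lambdas assumed sorted descending so warm starts densify gradually
  mat W = S;
  mat B = zeros<mat>(p, p);
  mat Theta = zeros<mat>(p, p);
  cube K(p, p, nl);
  Rcpp::LogicalVector ok(nl);
  for (int m = 0; m < nl; m++) {
    bool good = glasso_one(S, lambdas[m], W, B, Theta, maxit, tol);
    ok[m] = good;
    K.slice(m) = Theta;
    if (!good) { // reset the warm start so later points are unaffected
      W = S;
      B.zeros();
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::_["K"] = K, Rcpp::_["ok"] = ok);
}
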