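#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Block coordinate descent for the graphical lasso with unpenalized
// diagonal. Works on the covariance scale: W approximates the inverse of
// the estimate; each column update solves the lasso subproblem
//   min_b  1/2 b' W11 b - s12' b + lambda ||b||_1
// by cyclic coordinate descent. Theta is recovered from (W, B) after each
// sweep; convergence is the relative max-change of Theta between sweeps.
// [[Rcpp::export]]
List glasso_bcd(const arma::mat& S, double lambda, double tol, int max_iter) {
  const int p = S.n_rows;
  arma::mat W = S;                 // diagonal stays fixed (unpenalized)
  arma::mat B(p, p, arma::fill::zeros);

  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  std::vector<arma::uvec> others(p);
  for (int j = 0; j < p; ++j) others[j] = arma::find(all != (unsigned) j);

  auto recover_theta = [&](arma::mat& theta) {
    for (int j = 0; j < p; ++j) {
      const arma::uvec& oj = others[j];
      arma::vec beta = B.col(j);
      arma::vec b = beta(oj);
      arma::vec w12 = W.col(j);
      double denom = W(j, j) - arma::dot(w12(oj), b);
      double tjj = 1.0 / denom;
      theta(j, j) = tjj;
      for (unsigned k = 0; k < oj.n_elem; ++k) {
        double v = b(k) == 0.0 ? 0.0 : -b(k) * tjj;
        theta(oj(k), j) = v;
      }
    }
  };

  arma::mat theta(p, p, arma::fill::zeros), theta_old(p, p, arma::fill::zeros);
  recover_theta(theta_old);

  bool converged = false;
  double delta = NA_REAL;
  int used = 0;
  const int inner_max = 1000;

  for (int sweep = 1; sweep <= max_iter; ++sweep) {
    for (int j = 0; j < p; ++j) {
      const arma::uvec& oj = others[j];
      arma::mat W11 = W(oj, oj);
      arma::vec s12 = S.col(j);
      s12 = s12(oj);
      arma::vec beta = B.col(j);
      arma::vec b = beta(oj);
      arma::vec q = W11 * b;       // maintained residual W11 %*% b
      double inner_thr = tol * 0.1 * std::max(arma::abs(s12).max(), 1e-12);
      for (int it = 0; it < inner_max; ++it) {
        double max_change = 0.0;
        for (unsigned k = 0; k < oj.n_elem; ++k) {
          double r = s12(k) - q(k) + W11(k, k) * b(k);
          double bk;
          if (r > lambda)       bk = (r - lambda) / W11(k, k);
          else if (r < -lambda) bk = (r + lambda) / W11(k, k);
          else                  bk = 0.0;
          double d = bk - b(k);
          if (d != 0.0) {
            q += W11.col(k) * d;
            b(k) = bk;
            max_change = std::max(max_change, std::fabs(d));
          }
        }
        if (max_change <= inner_thr) break;
      }
      arma::vec w12 = W11 * b;
      for (unsigned k = 0; k < oj.n_elem; ++k) {
        W(oj(k), j) = w12(k);
        W(j, oj(k)) = w12(k);
        B(oj(k), j) = b(k);
      }
    }
    recover_theta(theta);
    double scale = std::max(arma::abs(theta_old).max(), 1e-12);
    delta = arma::abs(theta - theta_old).max() / scale;
    used = sweep;
    if (delta < tol) { converged = true; break; }
    theta_old = theta;
  }

  return List::create(_["theta"] = theta, _["iterations"] = used,
                      _["converged"] = converged, _["delta"] = delta);
}
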