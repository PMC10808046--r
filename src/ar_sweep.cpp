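// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
using namespace Rcpp;

// AIC sweep over AR orders 1..max_lag by least squares. Each order p is fit
// on its own effective sample (t = p+1..n) so residual length is n - p.

// [[Rcpp::export(name = ".ar_sweep")]]
List ar_sweep(const arma::vec& x, int max_lag) {
  const int n = x.n_elem;
  double best_aic = R_PosInf;
  arma::vec best_res;
  arma::vec best_coef;
  int best_p = 0;
  double best_s2 = 0.0;
  for (int p = 1; p <= max_lag; ++p) {
    const int ne = n - p;
    arma::mat X(ne, p + 1);
    X.col(0).ones();
    for (int k = 1; k <= p; ++k)
      X.col(k) = x.subvec(p - k, n - 1 - k);
    arma::vec y = x.subvec(p, n - 1);
    arma::vec cf;
    if (!arma::solve(cf, X, y)) continue;
    arma::vec r = y - X * cf;
    const double rss = arma::dot(r, r);
    const double aic = ne * std::log(rss / ne) + 2.0 * (p + 1);
    if (aic < best_aic) {
      best_aic = aic;
      best_res = r;
      best_coef = cf;
      best_p = p;
      best_s2 = rss / ne;
    }
  }
  if (best_p == 0) stop("AR sweep failed for all orders");
  return List::create(_["residuals"] = best_res, _["lag"] = best_p,
                      _["coef"] = best_coef, _["aic"] = best_aic,
                      _["sigma2"] = best_s2);
}

// Bivariate VAR AIC sweep; AIC uses the log determinant of the residual
// covariance with 2(2p+1) parameters. Optional ridge stabilizes
// near-collinear pairs.

// [[Rcpp::export(name = ".var_sweep")]]
List var_sweep(const arma::vec& x, const arma::vec& y, int max_lag,
               double ridge = 0.0) {
  const int n = x.n_elem;
  double best_aic = R_PosInf;
  arma::mat best_res, best_coef;
  int best_p = 0;
  arma::mat best_S;
  for (int p = 1; p <= max_lag; ++p) {
    const int ne = n - p;
    const int ncol = 2 * p + 1;
    arma::mat X(ne, ncol);
    X.col(0).ones();
    for (int k = 1; k <= p; ++k) {
      X.col(2 * k - 1) = x.subvec(p - k, n - 1 - k);
      X.col(2 * k) = y.subvec(p - k, n - 1 - k);
    }
    arma::mat Y(ne, 2);
    Y.col(0) = x.subvec(p, n - 1);
    Y.col(1) = y.subvec(p, n - 1);
    arma::mat B;
    bool ok;
    if (ridge > 0.0) {
      arma::mat XtX = X.t() * X;
      XtX.diag() += ridge * XtX.diag().max();
      ok = arma::solve(B, XtX, X.t() * Y);
    } else {
      ok = arma::solve(B, X, Y);
    }
    if (!ok) continue;
    arma::mat R = Y - X * B;
    arma::mat S = (R.t() * R) / ne;
    double ldet, sign;
    arma::log_det(ldet, sign, S);
    if (sign <= 0) continue;
    const double aic = ne * ldet + 2.0 * (2.0 * ncol);
    if (aic < best_aic) {
      best_aic = aic;
      best_res = R;
      best_coef = B;
      best_p = p;
      best_S = S;
    }
  }
  if (best_p == 0) stop("VAR sweep failed for all orders");
  return List::create(_["residuals"] = best_res, _["lag"] = best_p,
                      _["coef"] = best_coef, _["aic"] = best_aic,
                      _["sigma"] = best_S);
}
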