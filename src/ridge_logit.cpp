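// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// L2-regularised logistic regression by damped IRLS (Newton steps).
// The intercept (first coefficient) is unpenalised. X has no intercept
// column; y01 in {0,1}. Returns (d+1)-vector: intercept, then weights.

static arma::vec irls_fit(const arma::mat& X, const arma::vec& y,
                          double lambda, int maxit, double tol,
                          arma::vec beta) {
  int d = X.n_cols;
  arma::mat P(d + 1, d + 1, arma::fill::zeros);
  P.submat(1, 1, d, d).eye();
  P *= lambda;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = beta(0) + X * beta.subvec(1, d);
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec wt = mu % (1.0 - mu) + 1e-10;
    arma::vec r = y - mu;
    // gradient and Hessian of the penalised log-likelihood
    arma::vec g(d + 1);
    g(0) = arma::accu(r);
    g.subvec(1, d) = X.t() * r;
    g -= P * beta;
    arma::mat Xw = X.each_col() % wt;
    arma::mat H(d + 1, d + 1);
    H(0, 0) = arma::accu(wt);
    H.submat(0, 1, 0, d) = arma::sum(Xw, 0);
    H.submat(1, 0, d, 0) = H.submat(0, 1, 0, d).t();
    H.submat(1, 1, d, d) = X.t() * Xw;
    H += P;
    arma::vec step = arma::solve(H, g, arma::solve_opts::likely_sympd);
    double sn = arma::norm(step, "inf");
    if (sn > 5.0) step *= 5.0 / sn;  // damping for separable data
    beta += step;
    if (sn < tol) break;
  }
  return beta;
}

//' @noRd
// [[Rcpp::export(name = ".ridge_logit_cpp")]]
arma::vec ridge_logit_cpp(const arma::mat& X, const arma::vec& y01,
                          double lambda, int maxit = 50,
                          double tol = 1e-8) {
  arma::vec beta(X.n_cols + 1, arma::fill::zeros);
  return irls_fit(X, y01, lambda, maxit, tol, beta);
}

// Exact leave-one-trial-out decision values: for each trial, refit on
// all rows whose trial id differs (warm-started at the full-data fit)
// and return the mean linear decision value over the held-out rows.
//' @noRd
// [[Rcpp::export(name = ".loo_decisions_cpp")]]
arma::vec loo_decisions_cpp(const arma::mat& X, const arma::vec& y01,
                            const arma::ivec& trial, int n_trials,
                            double lambda, int maxit = 25,
                            double tol = 1e-6) {
  int d = X.n_cols;
  arma::vec full = irls_fit(X, y01, lambda, 2 * maxit, tol,
                            arma::vec(d + 1, arma::fill::zeros));
  arma::vec out(n_trials);
  for (int tr = 0; tr < n_trials; ++tr) {
    arma::uvec keep = arma::find(trial != tr);
    arma::uvec held = arma::find(trial == tr);
    arma::vec beta = irls_fit(X.rows(keep), y01.elem(keep), lambda,
                              maxit, tol, full);
    arma::vec eta = beta(0) + X.rows(held) * beta.subvec(1, d);
    out(tr) = arma::mean(eta);
  }
  return out;
}
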