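// Penalized (l2) logistic regression fitted by Newton/IRLS, plus the
// per-timepoint decoding loop. The penalty convention matches the common
// machine-learning parameterization: minimize
//   sum_i w_i * logloss_i + (1 / (2C)) * ||beta||^2
// with an unpenalized intercept. The ridge term makes the objective
// strictly concave, so plain Newton steps converge even on separable data.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// penalized negative log-likelihood, numerically stable in eta
static double pen_deviance(const mat& Xa, const vec& y, const vec& w,
                           const vec& pen, const vec& beta) {
  vec eta = Xa * beta;
  double f = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i);
    double lp = (e > 30.0) ? e : std::log1p(std::exp(e));
    f += w(i) * (lp - y(i) * e);
  }
  return f + 0.5 * dot(pen, beta % beta);
}

static vec irls_fit_from(const mat& X, const vec& y, const vec& w, double C,
                         int max_iter, double tol, vec beta) {
  uword n = X.n_rows, p = X.n_cols;
  mat Xa(n, p + 1);
  Xa.col(0).ones();
  if (p > 0) Xa.cols(1, p) = X;
  vec pen(p + 1);
  pen.fill(1.0 / C);
  pen(0) = 0.0;
  double f_cur = pen_deviance(Xa, y, w, pen, beta);
  for (int it = 0; it < max_iter; ++it) {
    vec mu = 1.0 / (1.0 + exp(-(Xa * beta)));
    vec grad = Xa.t() * (w % (mu - y)) + pen % beta;
    vec wt = w % mu % (1.0 - mu) + 1e-10;
    mat H = Xa.t() * (Xa.each_col() % wt);
    H.diag() += pen;
    vec step = solve(H, grad, solve_opts::likely_sympd);
    // backtracking: the penalized deviance is strictly convex, so a damped
    // Newton step always finds descent even from a saturated warm start
    double f_new = pen_deviance(Xa, y, w, pen, beta - step);
    int halvings = 0;
    while (f_new > f_cur && halvings < 30) {
      step *= 0.5;
      f_new = pen_deviance(Xa, y, w, pen, beta - step);
      ++halvings;
    }
    beta -= step;
    f_cur = f_new;
    if (norm(step, "inf") < tol) break;
  }
  return beta;
}

static vec irls_fit(const mat& X, const vec& y, const vec& w, double C,
                    int max_iter, double tol) {
  return irls_fit_from(X, y, w, C, max_iter, tol,
                       vec(X.n_cols + 1, fill::zeros));
}

// [[Rcpp::export]]
arma::vec cpp_ridge_logistic(const arma::mat& X, const arma::vec& y,
                             const arma::vec& w, double C = 1.0,
                             int max_iter = 50, double tol = 1e-8) {
  return irls_fit(X, y, w, C, max_iter, tol);
}

// Xtr, Xte: trials x features x time cubes on a common grid. Fits one
// classifier per time slice on (Xtr, y) and returns the predicted
// probability of the positive class for every test trial and timepoint.
// [[Rcpp::export]]
arma::mat cpp_decode_timepoints(const arma::cube& Xtr, const arma::vec& y,
                                const arma::vec& w, const arma::cube& Xte,
                                double C = 1.0, int max_iter = 50,
                                double tol = 1e-8) {
  uword T = Xtr.n_slices;
  mat probs(Xte.n_rows, T);
  for (uword t = 0; t < T; ++t) {
    vec beta = irls_fit(Xtr.slice(t), y, w, C, max_iter, tol);
    vec eta = beta(0) + Xte.slice(t) * beta.subvec(1, beta.n_elem - 1);
    probs.col(t) = 1.0 / (1.0 + exp(-eta));
  }
  return probs;
}

// Same loop on raw sensor cubes: the (already fitted) standardizer + PCA
// projection x * W - shift is applied per slice, and the Newton solver is
// warm-started from the previous timepoint's solution (adjacent slices are
// strongly correlated, which roughly halves the iteration count).
// [[Rcpp::export]]
arma::mat cpp_decode_raw(const arma::cube& Xtr, const arma::mat& W,
                         const arma::rowvec& shift, const arma::vec& y,
                         const arma::vec& w, const arma::cube& Xte,
                         double C = 1.0, int max_iter = 50,
                         double tol = 1e-8) {
  uword T = Xtr.n_slices;
  mat probs(Xte.n_rows, T);
  vec beta(W.n_cols + 1, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = Xtr.slice(t) * W;
    A.each_row() -= shift;
    mat B = Xte.slice(t) * W;
    B.each_row() -= shift;
    beta = irls_fit_from(A, y, w, C, max_iter, tol, beta);
    vec eta = beta(0) + B * beta.subvec(1, beta.n_elem - 1);
    probs.col(t) = 1.0 / (1.0 + exp(-eta));
  }
  return probs;
}
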