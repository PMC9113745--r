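// Fast logistic-regression Wald tests for the min-p permutation procedure.
// IRLS with a small ridge safeguard against separation; agreement with
// stats::glm is asserted in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// IRLS logistic fit; returns Wald p-value of coefficient `which`
// (0-based). ridge > 0 stabilizes separated fits.
static double logit_wald_p(const mat& X, const vec& y, unsigned which,
                           double ridge = 0.0) {
  const unsigned p = X.n_cols;
  vec beta(p, fill::zeros);
  mat XtWX(p, p);
  bool ok = false;
  for (int it = 0; it < 50; ++it) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    XtWX = X.t() * (X.each_col() % w);
    if (ridge > 0) XtWX.diag() += ridge;
    vec grad = X.t() * (y - mu);
    if (ridge > 0) grad -= ridge * beta;
    vec step;
    if (!solve(step, XtWX, grad)) return NA_REAL;
    beta += step;
    if (norm(step, "inf") < 1e-8) { ok = true; break; }
    if (!beta.is_finite()) return NA_REAL;
  }
  (void)ok;
  mat cov;
  if (!inv_sympd(cov, XtWX)) {
    if (!inv(cov, XtWX)) return NA_REAL;
  }
  double se = std::sqrt(cov(which, which));
  if (!std::isfinite(se) || se <= 0) return NA_REAL;
  double z = beta(which) / se;
  return 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
}

// [[Rcpp::export]]
Rcpp::List cpp_logit_fit(const arma::mat& X, const arma::vec& y,
                         double ridge = 0.0) {
  const unsigned p = X.n_cols;
  vec beta(p, fill::zeros);
  mat XtWX(p, p);
  for (int it = 0; it < 100; ++it) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    XtWX = X.t() * (X.each_col() % w);
    if (ridge > 0) XtWX.diag() += ridge;
    vec grad = X.t() * (y - mu);
    if (ridge > 0) grad -= ridge * beta;
    vec step = solve(XtWX, grad);
    beta += step;
    if (norm(step, "inf") < 1e-10) break;
  }
  mat cov = inv(XtWX);
  vec se = sqrt(cov.diag());
  vec z = beta / se;
  vec pv(p);
  for (unsigned j = 0; j < p; ++j)
    pv(j) = 2.0 * R::pnorm(-std::fabs(z(j)), 0.0, 1.0, 1, 0);
  return Rcpp::List::create(Rcpp::Named("coef") = beta,
                            Rcpp::Named("se") = se,
                            Rcpp::Named("p") = pv);
}

// Observed Wald p per channel plus the null min-p distribution over
// group-label permutations. `metric`: n x C (NaN = removed outlier);
// `covar`: n x k (age, sex, ...); `perms`: n x R permuted row indices
// (1-based, generated in R so seeding stays with R's RNG).
// [[Rcpp::export]]
Rcpp::List cpp_perm_minp(const arma::mat& metric, const arma::vec& y,
                         const arma::mat& covar,
                         const arma::imat& perms) {
  const unsigned n = metric.n_rows, C = metric.n_cols,
    R = perms.n_cols, k = covar.n_cols;
  vec obs_p(C, fill::value(NA_REAL));
  vec min_p(R, fill::value(datum::inf));

  for (unsigned c = 0; c < C; ++c) {
    vec mcol = metric.col(c);
    uvec keep = find_finite(mcol);
    if (keep.n_elem < k + 3) continue;
    const unsigned m = keep.n_elem;
    mat X(m, 2 + k);
    X.col(0).ones();
    X.col(1) = mcol(keep);
    for (unsigned j = 0; j < k; ++j) {
      vec ccol = covar.col(j);
      X.col(2 + j) = ccol(keep);
    }
    vec yk = y(keep);
    obs_p(c) = logit_wald_p(X, yk, 1, 1e-8);
    vec yp(m);
    for (unsigned r = 0; r < R; ++r) {
      // permuted labels, restricted to this channel's complete cases
      for (unsigned i = 0; i < m; ++i)
        yp(i) = y(perms(keep(i), r) - 1);
      double p = logit_wald_p(X, yp, 1, 1e-8);
      if (std::isfinite(p) && p < min_p(r)) min_p(r) = p;
    }
  }
  return Rcpp::List::create(Rcpp::Named("obs_p") = obs_p,
                            Rcpp::Named("min_p") = min_p);
}
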