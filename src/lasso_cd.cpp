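// Cyclic coordinate descent for the lasso, with warm-started penalty paths
// and cross-validation loops. Objective: (1/(2N)) ||y - X b||^2 + lambda ||b||_1.
// Columns of X are assumed standardized by the caller; within CV folds only
// re-centering (not re-scaling) is applied to the training rows.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One lasso fit at a single lambda. beta is modified in place.
// Returns the number of full sweeps used; sets converged.
static int cd_fit(const mat& X, const vec& y, double lambda, vec& beta,
                  double tol, int max_iter, bool& converged) {
  const double n = static_cast<double>(X.n_rows);
  const uword m = X.n_cols;
  vec xsq(m);
  for (uword j = 0; j < m; ++j) xsq[j] = dot(X.col(j), X.col(j)) / n;
  vec r = y - X * beta;
  converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    double maxdel = 0.0;
    for (uword j = 0; j < m; ++j) {
      if (xsq[j] <= 0.0) { beta[j] = 0.0; continue; }
      const double bj = beta[j];
      const double rho = dot(X.col(j), r) / n + xsq[j] * bj;
      const double bnew = soft(rho, lambda) / xsq[j];
      const double del = bnew - bj;
      if (del != 0.0) {
        r -= del * X.col(j);
        beta[j] = bnew;
        const double a = std::abs(del);
        if (a > maxdel) maxdel = a;
      }
    }
    if (maxdel < tol) { converged = true; ++it; break; }
  }
  return it;
}

// [[Rcpp::export(name = ".cd_lasso")]]
Rcpp::List cd_lasso(const arma::mat& X, const arma::vec& y, double lambda,
                    const arma::vec& beta_init, double tol, int max_iter) {
  vec beta = beta_init;
  bool conv;
  int it = cd_fit(X, y, lambda, beta, tol, max_iter, conv);
  // KKT residual: max over j of violation of |x_j' r / n| <= lambda (zero b)
  // or x_j' r / n = lambda * sign(b_j) (nonzero b)
  const double n = static_cast<double>(X.n_rows);
  vec r = y - X * beta;
  double kkt = 0.0;
  for (uword j = 0; j < X.n_cols; ++j) {
    const double g = dot(X.col(j), r) / n;
    double v;
    if (beta[j] == 0.0) v = std::max(0.0, std::abs(g) - lambda);
    else v = std::abs(g - lambda * ((beta[j] > 0) ? 1.0 : -1.0));
    if (v > kkt) kkt = v;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("iter") = it,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("kkt") = kkt);
}

// [[Rcpp::export(name = ".cd_lasso_path")]]
Rcpp::List cd_lasso_path(const arma::mat& X, const arma::vec& y,
                         const arma::vec& lambdas, double tol, int max_iter) {
  const uword m = X.n_cols, L = lambdas.n_elem;
  mat betas(m, L, fill::zeros);
  vec beta(m, fill::zeros);
  bool conv, all_conv = true;
  for (uword l = 0; l < L; ++l) {
    cd_fit(X, y, lambdas[l], beta, tol, max_iter, conv);
    if (!conv) all_conv = false;
    betas.col(l) = beta;
  }
  return Rcpp::List::create(Rcpp::Named("betas") = betas,
                            Rcpp::Named("converged") = all_conv);
}

// Cross-validation: for each fold, fit the whole path on the training rows
// (re-centered; training column means and training response mean absorbed
// into an intercept) and accumulate squared prediction errors on the held-out
// rows. Returns total squared error per lambda; caller divides by N.
// [[Rcpp::export(name = ".cd_lasso_cv")]]
arma::vec cd_lasso_cv(const arma::mat& X, const arma::vec& y,
                      const arma::vec& lambdas, const arma::ivec& fold_id,
                      int n_folds, double tol, int max_iter) {
  const uword L = lambdas.n_elem, m = X.n_cols;
  vec sse(L, fill::zeros);
  for (int f = 1; f <= n_folds; ++f) {
    uvec tr = find(fold_id != f);
    uvec te = find(fold_id == f);
    if (te.n_elem == 0) continue;
    mat Xtr = X.rows(tr);
    vec ytr = y.elem(tr);
    rowvec xm = mean(Xtr, 0);
    double ym = mean(ytr);
    Xtr.each_row() -= xm;
    ytr -= ym;
    mat Xte = X.rows(te);
    Xte.each_row() -= xm;
    vec yte = y.elem(te) - ym;
    vec beta(m, fill::zeros);
    bool conv;
    for (uword l = 0; l < L; ++l) {
      cd_fit(Xtr, ytr, lambdas[l], beta, tol, max_iter, conv);
      vec res = yte - Xte * beta;
      sse[l] += dot(res, res);
    }
  }
  return sse;
}
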