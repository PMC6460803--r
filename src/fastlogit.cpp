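// Batched binary logistic fits (IRLS) and midrank Mann-Whitney AUC.
// These back the all-pairs candidate-selection loop, which refits every
// candidate combination in every bootstrap resample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Midrank AUC: ties between a case and a control count 1/2. Cases and
// controls are sorted separately and merged with two monotone pointers,
// which is considerably cheaper than a full ranking of the pooled sample.
// group: 1 = case, 0 = control, anything else = excluded.
static double auc_core(const double* s, const int* group, int n,
                       std::vector<double>& ca, std::vector<double>& co) {
  ca.clear();
  co.clear();
  for (int k = 0; k < n; ++k) {
    if (group[k] == 1) ca.push_back(s[k]);
    else if (group[k] == 0) co.push_back(s[k]);
  }
  if (ca.empty() || co.empty()) return NA_REAL;
  std::sort(ca.begin(), ca.end());
  std::sort(co.begin(), co.end());
  const size_t n0 = co.size();
  size_t lt = 0, le = 0;
  double count = 0.0;
  for (double v : ca) {
    while (lt < n0 && co[lt] < v) ++lt;
    while (le < n0 && co[le] <= v) ++le;
    count += static_cast<double>(lt) + 0.5 * static_cast<double>(le - lt);
  }
  return count / (static_cast<double>(ca.size()) * static_cast<double>(n0));
}

// [[Rcpp::export]]
double cpp_auc(const NumericVector& scores, const IntegerVector& labels) {
  std::vector<double> ca, co;
  return auc_core(scores.begin(), labels.begin(), scores.size(), ca, co);
}

// AUC per column of a score matrix against one group vector
// (1 = case, 0 = control, -1 = excluded from the contrast).
// [[Rcpp::export]]
NumericVector cpp_auc_cols(const NumericMatrix& scores,
                           const IntegerVector& group) {
  const int n = scores.nrow(), nc = scores.ncol();
  NumericVector out(nc);
  std::vector<double> ca, co;
  ca.reserve(n);
  co.reserve(n);
  for (int c = 0; c < nc; ++c) {
    out[c] = auc_core(&scores(0, c), group.begin(), n, ca, co);
  }
  return out;
}

// IRLS for one design matrix (with intercept column already included).
// Returns false on non-convergence or diverging coefficients (separation).
static bool irls(const arma::mat& Z, const arma::vec& y, arma::vec& beta,
                 int maxit, double tol) {
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = Z * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec z = eta + (y - mu) / w;
    arma::mat Zw = Z.each_col() % w;
    arma::vec bnew;
    bool ok = arma::solve(bnew, Z.t() * Zw, Z.t() * (w % z),
                          arma::solve_opts::no_approx);
    if (!ok || !bnew.is_finite()) return false;
    double delta = arma::abs(bnew - beta).max();
    beta = bnew;
    if (arma::abs(beta).max() > 1e4) return false;  // separation
    if (delta < tol) return true;
  }
  return false;
}

// Fit one binary logistic model per candidate tuple. idx is an n_cand x m
// matrix of 1-based marker-column indices into X. Returns an (m+1) x n_cand
// coefficient matrix (intercept first) and a convergence flag per candidate.
// [[Rcpp::export]]
List cpp_fit_candidates(const arma::mat& X, const arma::uvec& y,
                        const arma::umat& idx, int maxit = 50,
                        double tol = 1e-9,
                        Nullable<NumericMatrix> init = R_NilValue) {
  const arma::uword nc = idx.n_rows, m = idx.n_cols, n = X.n_rows;
  arma::mat coefs(m + 1, nc, arma::fill::value(NA_REAL));
  LogicalVector converged(nc);
  arma::vec yd = arma::conv_to<arma::vec>::from(y);
  arma::mat warm;
  bool has_warm = init.isNotNull();
  if (has_warm) {
    warm = as<arma::mat>(init.get());
    has_warm = warm.n_rows == m + 1 && warm.n_cols == nc;
  }
  arma::mat Z(n, m + 1);
  Z.col(0).ones();
  arma::vec beta;
  for (arma::uword c = 0; c < nc; ++c) {
    for (arma::uword j = 0; j < m; ++j) Z.col(j + 1) = X.col(idx(c, j) - 1);
    if (has_warm && warm.col(c).is_finite()) beta = warm.col(c);
    else beta.zeros(m + 1);
    bool ok = irls(Z, yd, beta, maxit, tol);
    converged[c] = ok;
    if (beta.is_finite() && beta.n_elem == m + 1) coefs.col(c) = beta;
  }
  return List::create(_["coefs"] = coefs, _["converged"] = converged);
}

// Risk scores (fitted probabilities) for every candidate: n x n_cand matrix.
// [[Rcpp::export]]
arma::mat cpp_score_candidates(const arma::mat& X, const arma::umat& idx,
                               const arma::mat& coefs) {
  const arma::uword nc = idx.n_rows, m = idx.n_cols, n = X.n_rows;
  arma::mat out(n, nc);
  for (arma::uword c = 0; c < nc; ++c) {
    arma::vec eta(n, arma::fill::value(coefs(0, c)));
    for (arma::uword j = 0; j < m; ++j) {
      eta += coefs(j + 1, c) * X.col(idx(c, j) - 1);
    }
    out.col(c) = 1.0 / (1.0 + arma::exp(-eta));
  }
  return out;
}
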