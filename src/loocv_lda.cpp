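// Leave-one-out CV for the two-class Fisher discriminant.
// Per fold: pooled within-class scatter of the retained rows, ridge-stabilised
// solve for the weight vector, midpoint threshold between projected class
// means, held-out score. Mirrors the R path (fit_lda + predict) exactly up to
// floating-point rounding; kept in C++ because GA fitness evaluates it tens of
// thousands of times per run.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X: n x p, y: 0 = normal, 1 = cancer (positive class), ridge: relative ridge
// (actual ridge = ridge * trace(Sw) / p). Returns n x 2 matrix of
// (held-out score, fold threshold); prediction is score > threshold.
// [[Rcpp::export(name = ".cpp_loocv_scores")]]
arma::mat cpp_loocv_scores(const arma::mat& X, const arma::ivec& y, double ridge) {
  const uword n = X.n_rows, p = X.n_cols;
  if (y.n_elem != n) Rcpp::stop("label length does not match rows");
  mat out(n, 2);
  for (uword i = 0; i < n; ++i) {
    uvec keep = find(regspace<uvec>(0, n - 1) != i);
    mat Xt = X.rows(keep);
    ivec yt = y(keep);
    uvec i0 = find(yt == 0), i1 = find(yt == 1);
    if (i0.n_elem < 2 || i1.n_elem < 2)
      Rcpp::stop("each class needs >= 2 training samples in every fold");
    rowvec mu0 = mean(Xt.rows(i0), 0);
    rowvec mu1 = mean(Xt.rows(i1), 0);
    mat C0 = Xt.rows(i0); C0.each_row() -= mu0;
    mat C1 = Xt.rows(i1); C1.each_row() -= mu1;
    mat Sw = C0.t() * C0 + C1.t() * C1;
    if (ridge > 0) Sw.diag() += ridge * trace(Sw) / double(p);
    vec d = (mu1 - mu0).t();
    vec w;
    bool ok = solve(w, Sw, d, solve_opts::no_approx);
    if (!ok) Rcpp::stop("singular within-class scatter; use a positive ridge");
    if (dot(w, d) < 0) w = -w;  // orient so cancer scores higher
    double thr = 0.5 * (dot(w, mu1.t()) + dot(w, mu0.t()));
    out(i, 0) = dot(w, X.row(i).t());
    out(i, 1) = thr;
  }
  return out;
}
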