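#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// PLS1 coefficients (standardized-X scale) for a fixed component count.
// Orthogonal-scores NIPALS on pre-standardized X and centered y.
static arma::vec pls1_coef_arma(const arma::mat &Xs, const arma::vec &yc,
                                int ncomp) {
  const arma::uword p = Xs.n_cols;
  arma::mat Xc = Xs;
  arma::vec yr = yc;
  arma::mat W(p, ncomp), P(p, ncomp);
  arma::vec Q(ncomp);
  int a = 0;
  const double tol = 1e-12;
  while (a < ncomp) {
    arma::vec w = Xc.t() * yr;
    double nw = arma::norm(w);
    if (nw < tol) break;
    w /= nw;
    arma::vec t = Xc * w;
    double tt = arma::dot(t, t);
    if (tt < tol) break;
    arma::vec pl = Xc.t() * t / tt;
    double q = arma::dot(yr, t) / tt;
    Xc -= t * pl.t();
    yr -= q * t;
    W.col(a) = w; P.col(a) = pl; Q(a) = q;
    ++a;
  }
  if (a == 0) return arma::zeros<arma::vec>(p);
  arma::mat Wa = W.head_cols(a), Pa = P.head_cols(a);
  arma::vec Qa = Q.head(a);
  arma::vec b;
  if (!arma::solve(b, Pa.t() * Wa, Qa)) return arma::zeros<arma::vec>(p);
  return Wa * b;
}

// Bootstrap replicates of PLS1 coefficients: rows of `idx` (1-based) give
// the resampled subjects; each replicate re-standardizes X and re-centers
// y. Degenerate replicates (zero-variance column) come back as NaN rows
// so the caller can redraw them.
// [[Rcpp::export]]
NumericMatrix pls1_boot_cpp(NumericMatrix X, NumericVector y, int ncomp,
                            IntegerMatrix idx) {
  const int n = X.nrow(), p = X.ncol(), B = idx.nrow();
  arma::mat Xa(X.begin(), n, p, false);
  arma::vec ya(y.begin(), n, false);
  NumericMatrix out(B, p);
  for (int b = 0; b < B; ++b) {
    arma::uvec take(n);
    for (int i = 0; i < n; ++i) take(i) = idx(b, i) - 1;
    arma::mat Xb = Xa.rows(take);
    arma::vec yb = ya.elem(take);
    arma::rowvec mu = arma::mean(Xb, 0);
    arma::rowvec sd = arma::stddev(Xb, 0, 0);
    if (sd.min() <= 0 || arma::stddev(yb) <= 0) {
      for (int j = 0; j < p; ++j) out(b, j) = NA_REAL;
      continue;
    }
    Xb.each_row() -= mu;
    Xb.each_row() /= sd;
    arma::vec coef = pls1_coef_arma(Xb, yb - arma::mean(yb), ncomp);
    for (int j = 0; j < p; ++j) out(b, j) = coef(j);
  }
  return out;
}
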