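#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// NIPALS PLS1 on pre-centered data. Fills W (weights), P (x-loadings),
// q (y-loadings), T (scores); returns the number of components actually
// extracted (< A when the residual y becomes orthogonal to the residual X).
static int nipals_core(const arma::mat& Xc, const arma::vec& yc, int A,
                       arma::mat& W, arma::mat& P, arma::vec& q,
                       arma::mat& T) {
  arma::mat X = Xc;
  arma::vec y = yc;
  const arma::uword p = X.n_cols;
  W.zeros(p, A);
  P.zeros(p, A);
  q.zeros(A);
  T.zeros(X.n_rows, A);
  // scale-aware rank tolerance
  const double ref = arma::norm(Xc, "fro") * arma::norm(yc);
  const double tol = 1e-12 * std::max(ref, 1e-300);
  for (int a = 0; a < A; ++a) {
    arma::vec w = X.t() * y;
    const double nw = arma::norm(w);
    if (nw <= tol) return a;
    w /= nw;
    arma::vec t = X * w;
    const double tt = arma::dot(t, t);
    if (tt <= 1e-300) return a;
    arma::vec pv = X.t() * t / tt;
    const double qa = arma::dot(y, t) / tt;
    X -= t * pv.t();
    y -= qa * t;
    W.col(a) = w;
    P.col(a) = pv;
    q(a) = qa;
    T.col(a) = t;
  }
  return A;
}

// Regression coefficients on centered data for every component count
// 1..A: B.col(a-1) = W_a (P_a' W_a)^{-1} q_{1:a}.
static arma::mat betas_all(const arma::mat& W, const arma::mat& P,
                           const arma::vec& q, int A) {
  arma::mat B(W.n_rows, A, arma::fill::zeros);
  arma::mat M = P.head_cols(A).t() * W.head_cols(A);
  for (int a = 1; a <= A; ++a) {
    arma::vec z = arma::solve(M.submat(0, 0, a - 1, a - 1), q.head(a),
                              arma::solve_opts::fast);
    B.col(a - 1) = W.head_cols(a) * z;
  }
  return B;
}

// [[Rcpp::export]]
List cpp_pls_fit(const arma::mat& X, const arma::vec& y, int A) {
  const arma::rowvec xm = arma::mean(X, 0);
  const double ym = arma::mean(y);
  arma::mat Xc = X.each_row() - xm;
  arma::vec yc = y - ym;
  arma::mat W, P, T;
  arma::vec q;
  const int got = nipals_core(Xc, yc, A, W, P, q, T);
  if (got == 0) {
    return List::create(_["ncomp"] = 0);
  }
  arma::mat B = betas_all(W, P, q, got);
  return List::create(
      _["ncomp"] = got, _["xmean"] = arma::vec(xm.t()), _["ymean"] = ym,
      _["W"] = arma::mat(W.head_cols(got)),
      _["P"] = arma::mat(P.head_cols(got)),
      _["q"] = arma::vec(q.head(got)),
      _["T"] = arma::mat(T.head_cols(got)), _["B"] = B);
}

// Leave-one-out predictions for all component counts 1..Amax.
// preds(i, a-1) = prediction of sample i from the model fitted without it,
// using a components; NaN where that fold could not extract a components.
// [[Rcpp::export]]
List cpp_pls_loocv(const arma::mat& X, const arma::vec& y, int Amax) {
  const arma::uword n = X.n_rows;
  arma::mat preds(n, Amax);
  preds.fill(arma::datum::nan);
  int amin = Amax;
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat Xi = X;
    arma::vec yi = y;
    Xi.shed_row(i);
    yi.shed_row(i);
    const arma::rowvec xm = arma::mean(Xi, 0);
    const double ym = arma::mean(yi);
    arma::mat Xc = Xi.each_row() - xm;
    arma::vec yc = yi - ym;
    arma::mat W, P, T;
    arma::vec q;
    const int got = nipals_core(Xc, yc, Amax, W, P, q, T);
    if (got < amin) amin = got;
    if (got == 0) continue;
    arma::mat B = betas_all(W, P, q, got);
    const arma::rowvec xc = X.row(i) - xm;
    for (int a = 0; a < got; ++a)
      preds(i, a) = ym + arma::dot(xc, B.col(a));
  }
  return List::create(_["preds"] = preds, _["amin"] = amin);
}
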