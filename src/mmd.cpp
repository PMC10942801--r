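// Fused multi-scale Gaussian-kernel MMD^2 (biased V-statistic) with
// gradients with respect to both samples. Hot path of the transfer loss:
// called once per masked cluster pair, per layer, per epoch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat sqdist(const mat& A, const mat& B) {
  vec an = sum(square(A), 1);
  vec bn = sum(square(B), 1);
  mat d = repmat(an, 1, B.n_rows) + repmat(bn.t(), A.n_rows, 1) -
          2.0 * (A * B.t());
  d.elem(find(d < 0)).zeros();
  return d;
}

// Accumulate K = sum_s exp(-D/(2 s2 m_s)) and W = sum_s exp(.)/(s2 m_s)
// in one pass over D.
static void kernel_weights(const mat& D, double s2, const vec& mults,
                           mat& K, mat& W) {
  K.zeros(D.n_rows, D.n_cols);
  W.zeros(D.n_rows, D.n_cols);
  for (uword s = 0; s < mults.n_elem; ++s) {
    const double denom = s2 * mults[s];
    mat E = exp(D / (-2.0 * denom));
    K += E;
    W += E / denom;
  }
}

// [[Rcpp::export(name = ".mmd2_grad_cpp")]]
Rcpp::List mmd2_grad_cpp(const arma::mat& A, const arma::mat& B,
                         double s2, const arma::vec& mults,
                         bool want_grad) {
  const double n = A.n_rows, m = B.n_rows;
  mat Kaa, Waa, Kbb, Wbb, Kab, Wab;
  kernel_weights(sqdist(A, A), s2, mults, Kaa, Waa);
  kernel_weights(sqdist(B, B), s2, mults, Kbb, Wbb);
  kernel_weights(sqdist(A, B), s2, mults, Kab, Wab);
  const double value = accu(Kaa) / (n * n) + accu(Kbb) / (m * m) -
                       2.0 * accu(Kab) / (n * m);
  if (!want_grad)
    return Rcpp::List::create(Rcpp::Named("value") = value);
  mat gA = -(2.0 / (n * n)) * (diagmat(sum(Waa, 1)) * A - Waa * A) +
            (2.0 / (n * m)) * (diagmat(sum(Wab, 1)) * A - Wab * B);
  mat gB = -(2.0 / (m * m)) * (diagmat(sum(Wbb, 1)) * B - Wbb * B) +
            (2.0 / (n * m)) * (diagmat(sum(Wab, 0).t()) * B - Wab.t() * A);
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("gA") = gA,
                            Rcpp::Named("gB") = gB);
}

// Median of the pooled pairwise squared distances (upper triangle),
// the median-heuristic bandwidth. For large samples the median is taken
// over a deterministic strided subset of max_rows rows: the heuristic only
// has to track the embedding's scale, not be exact.
// [[Rcpp::export(name = ".median_sqdist_cpp")]]
double median_sqdist_cpp(const arma::mat& X, int max_rows = 512) {
  const uword n = X.n_rows;
  if (n < 2) return 1.0;
  mat Xs;
  if ((int)n > max_rows) {
    uvec idx = conv_to<uvec>::from(
      floor(linspace(0, n - 1, max_rows)));
    Xs = X.rows(idx);
  } else {
    Xs = X;
  }
  mat d = sqdist(Xs, Xs);
  const uword ns = d.n_rows;
  vec v(ns * (ns - 1) / 2);
  uword k = 0;
  for (uword j = 1; j < ns; ++j)
    for (uword i = 0; i < j; ++i) v[k++] = d(i, j);
  return median(v);
}
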