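#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Bray-Curtis similarity 2A/(sum_i + sum_j) over all row pairs.
// Columns may be pre-scaled by branch lengths, which turns this into the
// length-weighted tree variant (min(l*x, l*y) = l*min(x, y)).
// [[Rcpp::export]]
NumericMatrix pair_bray_matrix(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix s(n, n);
  NumericVector tot(n);
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    for (int k = 0; k < p; ++k) t += x(i, k);
    tot[i] = t;
    s(i, i) = 1.0;
  }
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double a = 0.0;
      for (int k = 0; k < p; ++k)
        a += std::min(x(i, k), x(j, k));
      double denom = tot[i] + tot[j];
      double v = denom > 0 ? 2.0 * a / denom : NA_REAL;
      s(i, j) = v;
      s(j, i) = v;
    }
  }
  return s;
}

// Shared/unique abundance components for all row pairs: A = sum min,
// B = unique to row i, C = unique to row j (upper triangle; lower mirrors
// with B and C swapped).
// [[Rcpp::export]]
List pair_abc_matrices(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix A(n, n), B(n, n), C(n, n);
  NumericVector tot(n);
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    for (int k = 0; k < p; ++k) t += x(i, k);
    tot[i] = t;
  }
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double a = 0.0;
      for (int k = 0; k < p; ++k)
        a += std::min(x(i, k), x(j, k));
      A(i, j) = A(j, i) = a;
      B(i, j) = C(j, i) = tot[i] - a;
      C(i, j) = B(j, i) = tot[j] - a;
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["C"] = C);
}
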