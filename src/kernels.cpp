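#include <Rcpp.h>
using namespace Rcpp;

// Correlation-sum log averages used by approximate entropy.
//
// For template length k (k = 1..kmax), phi_k is the mean over the
// N - k + 1 templates of log(C_i^k), where C_i^k is the fraction of
// templates within Chebyshev distance r of template i. Self-matches are
// counted, so every C_i^k is strictly positive and the logarithm is
// always defined.
//
// A single O(N^2) pass records, for each pair of start positions, the
// length of the initial run of per-sample matches (capped at kmax);
// every template length up to that run length gains one match.
// [[Rcpp::export]]
NumericVector apen_phi(NumericVector x, int kmax, double r) {
  const int n = x.size();
  if (kmax < 1) stop("kmax must be >= 1");
  if (n < kmax + 1) stop("series shorter than longest template");

  // counts(k-1, i): matches of length-k template starting at i (0-based)
  IntegerMatrix counts(kmax, n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      int t = 0;
      while (t < kmax && i + t < n && j + t < n &&
             std::abs(x[i + t] - x[j + t]) <= r) {
        ++t;
      }
      for (int k = 1; k <= t; ++k) counts(k - 1, i) += 1;
    }
  }

  NumericVector phi(kmax);
  for (int k = 1; k <= kmax; ++k) {
    const int m = n - k + 1;  // number of templates of length k
    double acc = 0.0;
    for (int i = 0; i < m; ++i) {
      acc += std::log((double)counts(k - 1, i) / (double)m);
    }
    phi[k - 1] = acc / (double)m;
  }
  return phi;
}

// Linear IIR filter, direct form II transposed, with initial state.
// b and a must have equal length n (a[0] == 1); zi has length n - 1.
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  const int n = b.size();
  if (a.size() != n) stop("b and a must have equal length");
  if (zi.size() != n - 1) stop("zi must have length(b) - 1");
  const int nx = x.size();
  NumericVector y(nx);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < nx; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < n - 2; ++k) {
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    }
    z[n - 2] = b[n - 1] * xi - a[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}
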