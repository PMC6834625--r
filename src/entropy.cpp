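#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-matching counts for sample entropy.
// Templates of length m are taken at i = 0..N-m-1 (so every m-template has an
// (m+1)-sample extension); B counts ordered-distinct pairs matching at length
// m under the Chebyshev norm with tolerance r, A those also matching at m+1.
// Self-matches are excluded by construction (i < j, counted once per
// unordered pair).
// [[Rcpp::export(name = ".sampen_counts")]]
List sampen_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const int n = N - m;  // number of usable m-templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool match = true;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Phi_m for approximate entropy: mean over i of log(C_i^m), where C_i^m is
// the fraction of the N-m+1 templates (self included) within Chebyshev
// distance r of template i.
static double apen_phi(const NumericVector& x, int m, double r) {
  const int N = x.size();
  const int n = N - m + 1;
  std::vector<double> count(n, 1.0);  // self-match
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) { count[i] += 1.0; count[j] += 1.0; }
    }
  }
  double phi = 0.0;
  for (int i = 0; i < n; ++i) phi += std::log(count[i] / n);
  return phi / n;
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  return apen_phi(x, m, r) - apen_phi(x, m + 1, r);
}
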