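#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman convention):
// templates u_m(i), i = 1..N-m, Chebyshev distance, matches with |d| <= r,
// self-matches excluded. B = matches at length m, A = matches at length m+1.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of length-m templates with an (m+1)th point
  double A = 0.0, B = 0.0;
  if (nt < 2 || r <= 0.0) return NumericVector::create(_["A"] = 0, _["B"] = 0);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
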