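#include <Rcpp.h>
using namespace Rcpp;

// Template-match pair counts for sample entropy.
// B = pairs (i < j) whose length-m templates match under Chebyshev
// distance <= r; A = the same pairs matching at length m + 1. Indices run
// over 0..N-m-1 so every length-m template has a length-(m+1) extension,
// the standard convention that makes SampEn = -log(A/B).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;          // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}
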