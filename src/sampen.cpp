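#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy by direct template matching (Richman-Moorman convention):
// templates X(i) = {x_i, ..., x_{i+m-1}}, i = 1..N-m for both lengths m and
// m+1 so the two counts share a denominator; Chebyshev distance; strict
// d < r; self-matches excluded (i != j). Returns -ln(A/B) where B counts
// length-m matches and A length-(m+1) matches. A == 0 yields +Inf; B == 0
// yields NaN (caller treats both as degenerate).
// [[Rcpp::export(name = ".sampenCpp")]]
double sampenCpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;              // number of templates of length m+1
  if (nt < 2) return NA_REAL;
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        double d = x[i + k] - x[j + k];
        if (d < 0) d = -d;
        if (d >= r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      double d = x[i + m] - x[j + m];
      if (d < 0) d = -d;
      if (d < r) ++A;
    }
  }
  if (B == 0) return R_NaN;
  if (A == 0) return R_PosInf;
  return -std::log((double)A / (double)B);
}
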