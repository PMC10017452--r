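#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman convention):
// among the N - m templates x[i..i+m-1] (i = 0..N-m-1), count ordered pairs
// i < j whose Chebyshev distance is <= r at length m (B) and at length m + 1
// (A).  Self-matches are excluded by construction.  Both counts use the same
// template index range so A's templates are a strict extension of B's.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of length-m templates that extend to m+1
  const double *px = x.begin();
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    const double *xi = px + i;
    for (int j = i + 1; j < nt; ++j) {
      const double *xj = px + j;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(xi[k] - xj[k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(xi[m] - xj[m]) <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
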