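#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

// Sample entropy by direct template counting (Richman & Moorman form).
//
// Templates of length m are taken at i = 0..n-m-1, so every template has an
// (m+1)-th point and the same n-m templates enter both counts. B counts
// unordered pairs (i < j) whose length-m templates match within tolerance r
// under the Chebyshev (max-abs) distance; A counts the subset that still
// matches at length m+1. Self-matches are excluded by construction.
// SampEn = -ln(A / B); A == 0 or B == 0 is undefined and returned as NA so
// callers can flag it instead of propagating -Inf.
//
// Template pairs are enumerated through an index sort on the first template
// element: only pairs already matching there are visited (a two-pointer
// sweep), which prunes most of the O(n^2) pair space without changing the
// counts.
//
// [[Rcpp::export]]
double sampen_count(Rcpp::NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1 || n < m + 2) return NA_REAL;
  const int nt = n - m;  // number of usable templates
  std::vector<int> ord(nt);
  for (int i = 0; i < nt; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  long long A = 0, B = 0;
  int lo = 0;
  for (int a = 1; a < nt; ++a) {
    const int i = ord[a];
    const double xi = x[i];
    while (x[ord[lo]] < xi - r) ++lo;
    for (int bpos = lo; bpos < a; ++bpos) {
      const int j = ord[bpos];
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}
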