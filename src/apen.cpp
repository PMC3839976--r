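#include <Rcpp.h>
#include <cmath>
#include <vector>

// Pincus approximate entropy ApEn(m, r) of a single series.
// phi(mm) is the mean log fraction of templates of length mm within
// Chebyshev distance r (self-matches included, as in the original
// definition); ApEn = phi(m) - phi(m + 1). Matches are counted once
// per unordered pair and mirrored, then the trailing template (present
// only at length m) is handled separately.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(Rcpp::NumericVector xv, int m, double r) {
  const int n = xv.size();
  if (n < m + 3) return NA_REAL;
  const double* x = REAL(xv);
  const int nt1 = n - m + 1;          // templates of length m
  const int nt2 = n - m;              // templates of length m + 1
  std::vector<int> c1(nt1, 1), c2(nt2, 1);   // self matches
  for (int i = 0; i < nt1; ++i) {
    for (int j = i + 1; j < nt1; ++j) {
      bool ok = true;
      for (int t = 0; t < m; ++t) {
        if (std::fabs(x[i + t] - x[j + t]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++c1[i]; ++c1[j];
      if (j < nt2 && std::fabs(x[i + m] - x[j + m]) <= r) {
        ++c2[i]; ++c2[j];
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < nt1; ++i)
    phi1 += std::log(static_cast<double>(c1[i]) / nt1);
  phi1 /= nt1;
  for (int i = 0; i < nt2; ++i)
    phi2 += std::log(static_cast<double>(c2[i]) / nt2);
  phi2 /= nt2;
  return phi1 - phi2;
}
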