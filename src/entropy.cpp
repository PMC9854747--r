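#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Approximate and sample entropy from one pass over ordered template pairs
// (Chebyshev distance). Both statistics count template matches at lengths m
// and m+1, so the pair distances are shared; only the normalizations differ:
//   AppEn  = Phi_m - Phi_{m+1}, self-matches included,
//            Phi_mm = mean_i log(C_i^mm / N_mm) over the N_mm templates;
//   SampEn = -log(A / B) over ordered pairs of the n - m templates that
//            admit an (m+1)-length extension, self-matches excluded.
// Returns c(AppEn, SampEn); SampEn is +Inf when A or B is zero.
// [[Rcpp::export]]
NumericVector appen_sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N1 = n - m + 1;  // templates of length m
  const int N2 = n - m;      // templates of length m+1
  std::vector<long long> c1(N1, 1);  // self-matches included
  std::vector<long long> c2(N2, 1);
  long long A = 0, B = 0;
  for (int i = 0; i < N1; ++i) {
    for (int j = i + 1; j < N1; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++c1[i]; ++c1[j];
      if (j < N2) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) {
          ++A;
          ++c2[i]; ++c2[j];
        }
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < N1; ++i) phi1 += std::log((double)c1[i] / N1);
  for (int i = 0; i < N2; ++i) phi2 += std::log((double)c2[i] / N2);
  double appen = phi1 / N1 - phi2 / N2;
  double sampen = (A == 0 || B == 0) ? R_PosInf
                                     : -std::log((double)A / (double)B);
  return NumericVector::create(appen, sampen);
}
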