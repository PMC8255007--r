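#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo ancestor-tracing method.
// sire/dam are 1-based row indices into a parents-first ordered pedigree,
// 0 for an unknown parent. Returns F (not the A diagonal).
// [[Rcpp::export(name = ".ml_inbreeding")]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n); // Mendelian-sampling variance of each animal

  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    double ds = (s > 0) ? 0.25 * (1.0 + F[s - 1]) : 0.0;
    double dd = (d > 0) ? 0.25 * (1.0 + F[d - 1]) : 0.0;
    D[i] = 1.0 - ds - dd;
    if (s == 0 || d == 0) {
      F[i] = 0.0;
      continue;
    }
    // trace ancestors from the highest index downward, accumulating the
    // gene-flow contributions L; F_i = sum(L_j^2 D_j) - 1
    std::map<int, double> L; // ordered by index
    L[i] = 1.0;
    double f = -1.0;
    while (!L.empty()) {
      auto it = std::prev(L.end());
      int j = it->first;
      double lj = it->second;
      L.erase(it);
      f += lj * lj * D[j];
      int js = sire[j], jd = dam[j];
      if (js > 0) L[js - 1] += 0.5 * lj;
      if (jd > 0) L[jd - 1] += 0.5 * lj;
    }
    F[i] = f;
  }
  return F;
}
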