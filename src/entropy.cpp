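#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy (Pincus): ApEn(m, r) = Phi_m - Phi_{m+1} with
// Chebyshev distance and self-matches included.
// [[Rcpp::export]]
double apEnCpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for ApEn(m)");
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int N = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int cnt = 0;
      for (int j = 0; j < N; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double dd = std::fabs(x[i + k] - x[j + k]);
          if (dd > d) { d = dd; if (d > r) break; }
        }
        if (d <= r) ++cnt;
      }
      acc += std::log((double)cnt / N);
    }
    phi[s] = acc / N;
  }
  return phi[0] - phi[1];
}
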