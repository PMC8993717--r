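#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy with self-matches, shared template index range.
//
// C_m[i]  = #{ j in 1..N-m : max_{k<m}   |x[i+k]-x[j+k]| <= r }
// C_m1[i] = #{ j in 1..N-m : max_{k<m+1} |x[i+k]-x[j+k]| <= r }
// ApEn    = -(N-m)^{-1} sum_i log(C_m1[i]/C_m[i])
//
// Both counts run j over the same 1..N-m range so the ratio is a true
// conditional probability (<= 1) and the result is always >= 0.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int M = N - m;  // number of templates
  if (M < 2) return NA_REAL;

  std::vector<int> cm(M, 0), cm1(M, 0);
  const double *xp = REAL(x);

  for (int i = 0; i < M; ++i) {
    for (int j = i; j < M; ++j) {
      bool ok_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(xp[i + k] - xp[j + k]) > r) { ok_m = false; break; }
      }
      if (!ok_m) continue;
      cm[i]++; if (j != i) cm[j]++;
      if (std::fabs(xp[i + m] - xp[j + m]) <= r) {
        cm1[i]++; if (j != i) cm1[j]++;
      }
    }
  }

  double acc = 0.0;
  for (int i = 0; i < M; ++i) {
    acc += std::log((double)cm1[i] / (double)cm[i]);
  }
  return -acc / (double)M;
}
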