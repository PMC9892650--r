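#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mean pairwise fuzzy memberships for embedding dimensions m and m+1.
//
// Templates of length m and m+1 are both formed at offsets 0..N-m-1 (so the
// two averages run over the same number of template pairs), each template is
// baselined by its own mean, similarity is exp(-(d/r)^2) on the Chebyshev
// distance, and self-matches are excluded. Returns c(phi_m, phi_m1).
// [[Rcpp::export]]
NumericVector cpp_fuzzy_phi(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of templates in both dimensions
  if (nt < 2) stop("series too short for embedding dimension m");
  if (r <= 0) stop("similarity tolerance must be > 0");

  // baselined template matrices, column-major: tm[k + i*m], tm1[k + i*(m+1)]
  std::vector<double> tm((size_t)nt * m), tm1((size_t)nt * (m + 1));
  for (int i = 0; i < nt; ++i) {
    double s = 0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    double mu = s / m;
    for (int k = 0; k < m; ++k) tm[(size_t)i * m + k] = x[i + k] - mu;
    s += x[i + m];
    mu = s / (m + 1);
    for (int k = 0; k <= m; ++k) tm1[(size_t)i * (m + 1) + k] = x[i + k] - mu;
  }

  const double inv_r2 = 1.0 / (r * r);
  double acc_m = 0, acc_m1 = 0;
  for (int i = 0; i < nt - 1; ++i) {
    const double* ai = &tm[(size_t)i * m];
    const double* bi = &tm1[(size_t)i * (m + 1)];
    for (int j = i + 1; j < nt; ++j) {
      const double* aj = &tm[(size_t)j * m];
      double d = 0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(ai[k] - aj[k]);
        if (dd > d) d = dd;
      }
      acc_m += std::exp(-d * d * inv_r2);
      const double* bj = &tm1[(size_t)j * (m + 1)];
      d = 0;
      for (int k = 0; k <= m; ++k) {
        double dd = std::fabs(bi[k] - bj[k]);
        if (dd > d) d = dd;
      }
      acc_m1 += std::exp(-d * d * inv_r2);
    }
  }
  const double npairs = (double)nt * (nt - 1) / 2.0;
  return NumericVector::create(acc_m / npairs, acc_m1 / npairs);
}
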