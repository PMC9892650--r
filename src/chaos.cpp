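#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Mean log-divergence curve between nearest-neighbour trajectory pairs
// (Rosenstein-style). x is delay-embedded with dimension m and delay tau;
// each point's nearest neighbour is searched outside a Theiler exclusion
// window; the returned vector g[s] (s = 0..max_steps) is the mean of
// log(distance) after s discrete steps, over pairs still inside the series.
// Pairs at exactly zero distance are skipped.
// [[Rcpp::export]]
NumericVector cpp_lle_divergence(NumericVector x, int m, int tau, int theiler,
                                 int max_steps) {
  const int n = x.size();
  const int M = n - (m - 1) * tau;
  if (M < theiler + 2) stop("series too short for embedding");

  // nearest neighbour (squared Euclidean), Theiler exclusion
  std::vector<int> nn(M, -1);
  std::vector<double> best(M, R_PosInf);
  for (int i = 0; i < M; ++i) {
    double bi = best[i];
    int ni = nn[i];
    for (int j = i + theiler + 1; j < M; ++j) {
      double d2 = 0;
      for (int k = 0; k < m; ++k) {
        double dd = x[i + k * tau] - x[j + k * tau];
        d2 += dd * dd;
        if (d2 >= bi && d2 >= best[j]) break;
      }
      if (d2 < bi) { bi = d2; ni = j; }
      if (d2 < best[j]) { best[j] = d2; nn[j] = i; }
    }
    best[i] = bi;
    nn[i] = ni;
  }

  NumericVector g(max_steps + 1, NA_REAL);
  for (int s = 0; s <= max_steps; ++s) {
    double acc = 0;
    int cnt = 0;
    for (int i = 0; i < M; ++i) {
      int j = nn[i];
      if (j < 0 || i + s >= M || j + s >= M) continue;
      double d2 = 0;
      for (int k = 0; k < m; ++k) {
        double dd = x[i + s + k * tau] - x[j + s + k * tau];
        d2 += dd * dd;
      }
      if (d2 > 0) { acc += 0.5 * std::log(d2); ++cnt; }
    }
    if (cnt > 0) g[s] = acc / cnt;
  }
  return g;
}

// Correlation sums C_m(r) for embedding dimensions 1..mmax on a shared log
// radius grid (Chebyshev norm, Grassberger-Procaccia). Reference points are
// an evenly spaced subsample of at most nref embedded points; partners run
// over all points outside the Theiler window. Returns an mmax x nradii
// matrix of C values (fraction of pairs with distance <= r).
// [[Rcpp::export]]
NumericMatrix cpp_corr_sums(NumericVector x, int mmax, int tau, int theiler,
                            NumericVector radii, int nref) {
  const int n = x.size();
  const int M = n - (mmax - 1) * tau;
  const int nr = radii.size();
  if (M < theiler + 2) stop("series too short for embedding");
  for (int i = 1; i < nr; ++i)
    if (radii[i] <= radii[i - 1]) stop("radii must be strictly increasing");

  const int step = std::max(1, M / std::max(1, nref));
  std::vector<std::vector<double>> hist(mmax, std::vector<double>(nr + 1, 0.0));
  std::vector<double> npairs(mmax, 0.0);

  for (int i = 0; i < M; i += step) {
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = 0;
      int idx = 0; // first radius >= d; only moves forward as d grows with k
      for (int k = 0; k < mmax; ++k) {
        double dd = std::fabs(x[i + k * tau] - x[j + k * tau]);
        if (dd > d) {
          d = dd;
          while (idx < nr && radii[idx] < d) ++idx;
        }
        hist[k][idx] += 1.0;
        npairs[k] += 1.0;
      }
    }
  }

  NumericMatrix C(mmax, nr);
  for (int k = 0; k < mmax; ++k) {
    double cum = 0;
    for (int r = 0; r < nr; ++r) {
      cum += hist[k][r];
      C(k, r) = npairs[k] > 0 ? cum / npairs[k] : NA_REAL;
    }
  }
  return C;
}
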