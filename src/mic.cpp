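#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Maximal information coefficient by the MINE-family approximate search:
// for every grid resolution (p columns x q rows) with p*q <= B = n^alpha,
// the y-axis is equipartitioned into q rows and the x-axis partition is
// optimised by dynamic programming over clumps (runs of consecutive points
// sharing a row, merged over tied x values, capped at c_par * p superclumps).
// Each grid's mutual information is normalised by log(min(p, q)); MIC is the
// maximum over both axis orientations.

static inline double xlogx(double p) { return p > 0 ? p * std::log(p) : 0.0; }

// entropy of a count vector with total tot
static double count_entropy(const std::vector<double>& cnt, double tot) {
  double h = 0;
  for (double c : cnt) h -= xlogx(c / tot);
  return h;
}

// Equipartition values into at most q rows, never splitting tied values.
// Returns row id per (sorted) rank and the number of distinct rows used.
static int equipartition(const std::vector<double>& v_sorted,
                         int q, std::vector<int>& row) {
  const int n = v_sorted.size();
  row.assign(n, 0);
  int i = 0, prev_row = 0;
  while (i < n) {
    int j = i;
    while (j < n && v_sorted[j] == v_sorted[i]) ++j; // tied block [i, j)
    int r = (int)((double)q * (i + (j - i) / 2.0) / n);
    if (r >= q) r = q - 1;
    if (r < prev_row) r = prev_row;
    for (int k = i; k < j; ++k) row[k] = r;
    prev_row = r;
    i = j;
  }
  // compress to consecutive ids
  int q_act = 0, last = -1;
  for (int k = 0; k < n; ++k) {
    if (row[k] != last) { last = row[k]; ++q_act; }
    row[k] = q_act - 1;
  }
  return q_act;
}

// One orientation: optimise x-axis partitions against y-axis equipartitions.
// Fills score[p][q] (1-based p,q) with max normalised MI seen.
static void char_matrix(const std::vector<double>& x,
                        const std::vector<double>& y,
                        int B, double c_par,
                        std::vector<std::vector<double>>& score) {
  const int n = x.size();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return y[a] < y[b]; });
  std::vector<double> y_sorted(n);
  for (int i = 0; i < n; ++i) y_sorted[i] = y[ord[i]];

  std::vector<int> xrank_order(n); // point indices sorted by x (ties by y)
  std::iota(xrank_order.begin(), xrank_order.end(), 0);
  std::sort(xrank_order.begin(), xrank_order.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  const int qmax = B / 2;
  for (int q = 2; q <= qmax; ++q) {
    std::vector<int> row_of_sorted;
    int q_act = equipartition(y_sorted, q, row_of_sorted);
    if (q_act < 2) continue;
    std::vector<int> row(n); // row id per original point index
    for (int i = 0; i < n; ++i) row[ord[i]] = row_of_sorted[i];

    const int p_max = std::max(2, B / q);

    // clumps in x-order: split where the row changes, but never inside a
    // run of tied x values
    std::vector<int> clump_size;
    std::vector<std::vector<double>> clump_rows; // row counts per clump
    {
      int i = 0;
      int cur = -2; // current clump's row (-1 = mixed)
      while (i < n) {
        int j = i;
        while (j < n && x[xrank_order[j]] == x[xrank_order[i]]) ++j;
        // tied-x block [i, j): one atomic unit
        int blk_row = row[xrank_order[i]];
        for (int k = i + 1; k < j; ++k)
          if (row[xrank_order[k]] != blk_row) { blk_row = -1; break; }
        bool merge = !clump_size.empty() && cur >= 0 && blk_row == cur;
        if (!merge) {
          clump_size.push_back(0);
          clump_rows.push_back(std::vector<double>(q_act, 0.0));
          cur = blk_row;
        }
        clump_size.back() += j - i;
        for (int k = i; k < j; ++k)
          clump_rows.back()[row[xrank_order[k]]] += 1.0;
        if (blk_row < 0) cur = -1;
        i = j;
      }
    }

    // superclumps: cap the number of DP blocks at c_par * p_max
    int khat = std::max(2, (int)(c_par * p_max));
    int k_all = clump_size.size();
    std::vector<int> sc_size;
    std::vector<std::vector<double>> sc_rows;
    if (k_all > khat) {
      double target = (double)n / khat;
      double acc = 0;
      for (int t = 0; t < k_all; ++t) {
        if (sc_size.empty() || acc >= target * (double)sc_size.size()) {
          sc_size.push_back(0);
          sc_rows.push_back(std::vector<double>(q_act, 0.0));
        }
        sc_size.back() += clump_size[t];
        for (int r = 0; r < q_act; ++r) sc_rows.back()[r] += clump_rows[t][r];
        acc += clump_size[t];
      }
    } else {
      sc_size = clump_size;
      sc_rows = clump_rows;
    }
    const int k = sc_size.size();
    if (k < 2) continue;

    // cumulative counts: c[t] points in first t blocks; cum[t][r] per row
    std::vector<double> csum(k + 1, 0.0);
    std::vector<std::vector<double>> cum(k + 1, std::vector<double>(q_act, 0.0));
    for (int t = 1; t <= k; ++t) {
      csum[t] = csum[t - 1] + sc_size[t - 1];
      for (int r = 0; r < q_act; ++r)
        cum[t][r] = cum[t - 1][r] + sc_rows[t - 1][r];
    }
    const double HQ = count_entropy(cum[k], csum[k]);

    // h(s,t): entropy of the row distribution inside blocks s+1..t
    auto slice_h = [&](int s, int t) {
      double tot = csum[t] - csum[s];
      if (tot <= 0) return 0.0;
      double h = 0;
      for (int r = 0; r < q_act; ++r)
        h -= xlogx((cum[t][r] - cum[s][r]) / tot);
      return h;
    };

    // DP over Ghat(t,l) = c_t * max_P [ -sum_cols (n_col/c_t) H(rows|col) ]
    const int lmax = std::min(p_max, k);
    std::vector<double> prev(k + 1), curr(k + 1);
    for (int t = 1; t <= k; ++t) prev[t] = -csum[t] * slice_h(0, t);
    for (int l = 2; l <= lmax; ++l) {
      for (int t = l; t <= k; ++t) {
        double best = R_NegInf;
        for (int s = l - 1; s < t; ++s) {
          double v = prev[s] - (csum[t] - csum[s]) * slice_h(s, t);
          if (v > best) best = v;
        }
        curr[t] = best;
      }
      // normalised MI for p = l columns, q_act rows
      double I = HQ + curr[k] / csum[k];
      double norm = std::log(std::min(l, q_act));
      if (norm > 0 && l * q_act <= B) {
        double v = I / norm;
        if ((int)score.size() > l && (int)score[l].size() > q_act &&
            v > score[l][q_act])
          score[l][q_act] = v;
      }
      std::swap(prev, curr);
    }
  }
}

// [[Rcpp::export]]
double cpp_mic(NumericVector xr, NumericVector yr, double alpha, double c_par) {
  const int n = xr.size();
  if (yr.size() != n) stop("series must have equal length");
  if (n < 20) stop("MIC requires at least 20 samples");
  std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());

  int B = (int)std::floor(std::pow((double)n, alpha));
  if (B < 4) B = 4;

  std::vector<std::vector<double>> sxy(B + 1, std::vector<double>(B + 1, 0.0));
  std::vector<std::vector<double>> syx(B + 1, std::vector<double>(B + 1, 0.0));
  char_matrix(x, y, B, c_par, sxy); // columns on x
  char_matrix(y, x, B, c_par, syx); // columns on y

  double mic = 0;
  for (int p = 2; p <= B; ++p)
    for (int q = 2; q <= B; ++q) {
      if (p * q > B) break;
      double v = std::max(sxy[p][q], syx[q][p]);
      if (v > mic) mic = v;
    }
  if (mic > 1) mic = 1; // guard against rounding just above 1
  return mic;
}
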