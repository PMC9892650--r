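#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Running minimum / maximum over a centred flat window of k samples,
// borders handled by replication. Monotonic-deque algorithm, O(n).
static NumericVector run_extremum(const NumericVector& x, int k, bool want_max) {
  const int n = x.size();
  if (k < 1) stop("window length must be >= 1");
  if (k > n) stop("structuring element longer than signal");
  const int half_left = (k - 1) / 2, half_right = k / 2;
  NumericVector out(n);
  std::deque<int> dq; // indices into padded series, values kept monotone

  // padded index p in [-half_left, n-1+half_right]; value at p clamps to [0, n-1]
  auto val = [&](int p) {
    if (p < 0) p = 0;
    if (p >= n) p = n - 1;
    return x[p];
  };
  int lo = -half_left; // left edge of current window (padded index)
  for (int p = -half_left; p < n + half_right; ++p) {
    double v = val(p);
    while (!dq.empty() &&
           (want_max ? val(dq.back()) <= v : val(dq.back()) >= v))
      dq.pop_back();
    dq.push_back(p);
    int centre = p - half_right; // window [centre-half_left, centre+half_right]
    if (centre >= 0) {
      lo = centre - half_left;
      while (dq.front() < lo) dq.pop_front();
      out[centre] = val(dq.front());
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_running_min(NumericVector x, int k) {
  return run_extremum(x, k, false);
}

// [[Rcpp::export]]
NumericVector cpp_running_max(NumericVector x, int k) {
  return run_extremum(x, k, true);
}
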