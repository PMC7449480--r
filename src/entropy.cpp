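#include <Rcpp.h>
using namespace Rcpp;

// Pincus approximate entropy, Chebyshev distance, self-matches included.
// phi_m = mean_i log(C_i^m), C_i^m = (#j: max|x[i+k]-x[j+k]| <= r) / (N-m+1)
//' @keywords internal
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for ApEn at this m");
  if (r <= 0) stop("tolerance r must be positive");
  double phi[2];
  for (int d = 0; d < 2; ++d) {
    int mm = m + d;
    int nv = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nv; ++i) {
      int cnt = 0;
      for (int j = 0; j < nv; ++j) {
        bool match = true;
        for (int k = 0; k < mm; ++k) {
          double diff = x[i + k] - x[j + k];
          if (diff < 0) diff = -diff;
          if (diff > r) { match = false; break; }
        }
        if (match) ++cnt;
      }
      acc += std::log((double)cnt / nv);
    }
    phi[d] = acc / nv;
  }
  return phi[0] - phi[1];
}

// LZ76 exhaustive-history production count (Kaspar & Schuster scan).
//' @keywords internal
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n < 1) stop("empty sequence");
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Maximum peak-to-peak amplitude over all sliding windows of w samples.
// Monotone-deque running max/min; O(n).
//' @keywords internal
// [[Rcpp::export]]
double roll_ptp_max_cpp(NumericVector x, int w) {
  int n = x.size();
  if (w < 2) stop("window must span at least 2 samples");
  if (w > n) w = n;
  std::deque<int> qmax, qmin;
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    while (!qmax.empty() && x[qmax.back()] <= x[i]) qmax.pop_back();
    qmax.push_back(i);
    while (!qmin.empty() && x[qmin.back()] >= x[i]) qmin.pop_back();
    qmin.push_back(i);
    if (qmax.front() <= i - w) qmax.pop_front();
    if (qmin.front() <= i - w) qmin.pop_front();
    if (i >= w - 1) {
      double ptp = x[qmax.front()] - x[qmin.front()];
      if (ptp > best) best = ptp;
    }
  }
  return best;
}
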