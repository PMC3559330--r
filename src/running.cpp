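#include <Rcpp.h>
#include <deque>
#include <algorithm>
using namespace Rcpp;

// Centered running quantile (type-7) with shrinking windows at the edges.
// width is in samples; the window at i is [i - width/2, i + width/2]
// clipped to the series.
// [[Rcpp::export]]
NumericVector run_quantile_center(NumericVector x, int width, double prob) {
  int n = x.size();
  if (width < 1) stop("width must be >= 1");
  if (prob < 0.0 || prob > 1.0) stop("prob must be in [0, 1]");
  NumericVector out(n);
  int half = width / 2;
  std::vector<double> buf;
  buf.reserve(width + 1);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half);
    int hi = std::min(n - 1, i + half);
    int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    double h = (m - 1) * prob;
    int k = (int)std::floor(h);
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double xk = buf[k];
    double res = xk;
    if (h > k && k + 1 <= m - 1) {
      double xk1 = *std::min_element(buf.begin() + k + 1, buf.end());
      res = xk + (h - k) * (xk1 - xk);
    }
    out[i] = res;
  }
  return out;
}

// Centered running maximum via a monotonic deque (O(n)).
// [[Rcpp::export]]
NumericVector run_max_center(NumericVector x, int width) {
  int n = x.size();
  if (width < 1) stop("width must be >= 1");
  NumericVector out(n);
  int half = width / 2;
  std::deque<int> dq;
  int r = -1;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half);
    int hi = std::min(n - 1, i + half);
    while (r < hi) {
      ++r;
      while (!dq.empty() && x[dq.back()] <= x[r]) dq.pop_back();
      dq.push_back(r);
    }
    while (!dq.empty() && dq.front() < lo) dq.pop_front();
    out[i] = x[dq.front()];
  }
  return out;
}

// Centered running minimum via a monotonic deque (O(n)).
// [[Rcpp::export]]
NumericVector run_min_center(NumericVector x, int width) {
  int n = x.size();
  if (width < 1) stop("width must be >= 1");
  NumericVector out(n);
  int half = width / 2;
  std::deque<int> dq;
  int r = -1;  // rightmost index pushed so far
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half);
    int hi = std::min(n - 1, i + half);
    while (r < hi) {
      ++r;
      while (!dq.empty() && x[dq.back()] >= x[r]) dq.pop_back();
      dq.push_back(r);
    }
    while (!dq.empty() && dq.front() < lo) dq.pop_front();
    out[i] = x[dq.front()];
  }
  return out;
}
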