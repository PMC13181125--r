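#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Centered running minimum with shrunken windows at the edges.
// window w in samples; at sample i the window is [i-h, i+h] clipped to the
// trace, h = w/2 (integer division).
// [[Rcpp::export]]
NumericVector run_min_c(NumericVector x, int w) {
  int n = x.size();
  int h = w / 2;
  NumericVector out(n);
  std::deque<int> q; // indices, values increasing
  int right = -1;
  for (int i = 0; i < n; ++i) {
    int hi = std::min(n - 1, i + h);
    while (right < hi) {
      ++right;
      while (!q.empty() && x[q.back()] >= x[right]) q.pop_back();
      q.push_back(right);
    }
    int lo = std::max(0, i - h);
    while (q.front() < lo) q.pop_front();
    out[i] = x[q.front()];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector run_max_c(NumericVector x, int w) {
  int n = x.size();
  int h = w / 2;
  NumericVector out(n);
  std::deque<int> q; // indices, values decreasing
  int right = -1;
  for (int i = 0; i < n; ++i) {
    int hi = std::min(n - 1, i + h);
    while (right < hi) {
      ++right;
      while (!q.empty() && x[q.back()] <= x[right]) q.pop_back();
      q.push_back(right);
    }
    int lo = std::max(0, i - h);
    while (q.front() < lo) q.pop_front();
    out[i] = x[q.front()];
  }
  return out;
}

// Non-negative AR(1) deconvolution (pool-adjacent-violators, no sparsity
// penalty). Fits c[t] = gamma * c[t-1] + s[t], s >= 0, minimizing
// ||c - y||^2; returns the event train s. Within a pool the fit decays
// exactly by gamma, so s is nonzero only at pool starts.
// [[Rcpp::export]]
NumericVector deconv_ar1_c(NumericVector y, double gamma) {
  int n = y.size();
  NumericVector s(n);
  if (n == 0) return s;
  std::vector<double> v(n), w(n);
  std::vector<int> t0(n), len(n);
  int np = 0; // number of pools
  for (int t = 0; t < n; ++t) {
    v[np] = y[t]; w[np] = 1.0; t0[np] = t; len[np] = 1;
    ++np;
    // merge while the new pool starts below the decayed continuation of the
    // previous pool (would require a negative event)
    while (np > 1) {
      double g = std::pow(gamma, (double)len[np - 2]);
      if (v[np - 1] / w[np - 1] >= g * v[np - 2] / w[np - 2]) break;
      v[np - 2] += g * v[np - 1];
      w[np - 2] += g * g * w[np - 1];
      len[np - 2] += len[np - 1];
      --np;
    }
  }
  double c_prev = 0.0;
  bool first = true;
  for (int p = 0; p < np; ++p) {
    double h = v[p] / w[p];
    if (h < 0.0) h = 0.0;
    double c = h;
    for (int k = 0; k < len[p]; ++k) {
      int t = t0[p] + k;
      if (k == 0) {
        s[t] = first ? c : c - gamma * c_prev;
        if (s[t] < 0.0) s[t] = 0.0;
        first = false;
      } else {
        s[t] = 0.0;
      }
      c_prev = c;
      c *= gamma;
    }
    c_prev = h * std::pow(gamma, (double)(len[p] - 1));
  }
  return s;
}
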