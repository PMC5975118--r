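#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Chebyshev (max-norm) k-nearest-neighbor distances by brute force.
// X is an N x d matrix (row-major copies below for cache locality). For the
// sample sizes used here (N <= 2^14, d <= 9) the O(N^2 d) scan with early
// exit is faster in practice than tree construction in high-ish d.

static inline double cheb_dist(const std::vector<double>& a, int i, int j,
                               int d, int n, double cutoff) {
  // columns stored contiguously: element (i, col) at a[col * n + i]
  double m = 0.0;
  for (int c = 0; c < d; ++c) {
    const double diff = std::abs(a[(size_t)c * n + i] - a[(size_t)c * n + j]);
    if (diff > m) {
      m = diff;
      if (m >= cutoff) return m;  // early exit: cannot be a k-NN
    }
  }
  return m;
}

static std::vector<double> flatten(const NumericMatrix& X) {
  std::vector<double> a(X.size());
  std::copy(X.begin(), X.end(), a.begin());
  return a;
}

// Distance from every point to its k-th nearest neighbor (max-norm,
// self excluded).
// [[Rcpp::export]]
NumericVector knn_dist_cpp(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k >= n) stop("need 1 <= k < number of points");
  const std::vector<double> a = flatten(X);
  NumericVector out(n);
  std::vector<double> heap;  // max-heap of current k smallest distances
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    heap.clear();
    double cutoff = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dist = cheb_dist(a, i, j, d, n, cutoff);
      if (dist < cutoff) {
        heap.push_back(dist);
        std::push_heap(heap.begin(), heap.end());
        if ((int)heap.size() > k) {
          std::pop_heap(heap.begin(), heap.end());
          heap.pop_back();
        }
        if ((int)heap.size() == k) cutoff = heap.front();
      }
    }
    out[i] = heap.front();
  }
  return out;
}

// For each point, count neighbors with max-norm distance strictly less than
// eps[i] (self excluded). Used for the KSG marginal counts n_x, n_y.
// [[Rcpp::export]]
IntegerVector range_count_cpp(NumericMatrix X, NumericVector eps) {
  const int n = X.nrow(), d = X.ncol();
  if (eps.size() != n) stop("eps must have one entry per point");
  const std::vector<double> a = flatten(X);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double e = eps[i];
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (cheb_dist(a, i, j, d, n, e) < e) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}
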