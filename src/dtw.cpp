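#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Accumulated-cost DTW with squared local cost and full (unconstrained)
// monotone alignment; returns sqrt of the minimal accumulated cost.
static double dtw_core(const double* x, int n, const double* y, int m) {
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double d = x[i - 1] - y[j - 1];
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[m]);
}

// [[Rcpp::export]]
double dtw_distance_cpp(NumericVector x, NumericVector y) {
  if (x.size() == 0 || y.size() == 0)
    stop("sequences must be non-empty");
  return dtw_core(x.begin(), x.size(), y.begin(), y.size());
}

// [[Rcpp::export]]
NumericMatrix pairwise_dtw_cpp(NumericMatrix traj) {
  int n = traj.nrow(), m = traj.ncol();
  // copy rows to contiguous buffers (R matrices are column-major)
  std::vector<double> rows((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      rows[(size_t)i * m + j] = traj(i, j);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_core(&rows[(size_t)i * m], m, &rows[(size_t)j * m], m);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
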