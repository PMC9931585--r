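#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Median filter with edge replication. Window is odd; rasters are small
// (tissue cores, <= a few thousand px per side) so a direct per-pixel
// sort is fast enough and trivially matches a brute-force definition.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(const NumericMatrix& x, const int window) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf.push_back(x(ii, jj));
        }
      }
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      out(i, j) = buf[buf.size() / 2];
    }
  }
  return out;
}

// Exact 1-D k-means on weighted distinct values via dynamic programming:
// optimal clusters are contiguous intervals of the sorted values, so the
// global SSE optimum is found exactly (no initialisation dependence).
// `values` must be sorted ascending, `weights` are positive counts.
// Returns 1-based cluster index per value, clusters ordered by mean.
// [[Rcpp::export(name = ".kmeans1d_cpp")]]
IntegerVector kmeans1d_cpp(const NumericVector& values,
                           const NumericVector& weights, const int k) {
  const int m = values.size();
  std::vector<double> cw(m + 1, 0.0), cwx(m + 1, 0.0), cwx2(m + 1, 0.0);
  for (int i = 0; i < m; ++i) {
    cw[i + 1] = cw[i] + weights[i];
    cwx[i + 1] = cwx[i] + weights[i] * values[i];
    cwx2[i + 1] = cwx2[i] + weights[i] * values[i] * values[i];
  }
  // SSE of interval (i..j], 0-based half open on prefix arrays
  auto sse = [&](int i, int j) {
    double w = cw[j] - cw[i];
    if (w <= 0.0) return 0.0;
    double s = cwx[j] - cwx[i];
    return (cwx2[j] - cwx2[i]) - s * s / w;
  };
  // dp[c][j]: min SSE of first j values in c clusters
  std::vector<std::vector<double>> dp(k + 1, std::vector<double>(m + 1, R_PosInf));
  std::vector<std::vector<int>> cut(k + 1, std::vector<int>(m + 1, 0));
  dp[0][0] = 0.0;
  for (int c = 1; c <= k; ++c) {
    for (int j = c; j <= m; ++j) {
      for (int i = c - 1; i < j; ++i) {
        double cand = dp[c - 1][i] + sse(i, j);
        if (cand < dp[c][j]) {
          dp[c][j] = cand;
          cut[c][j] = i;
        }
      }
    }
  }
  IntegerVector lab(m);
  int j = m;
  for (int c = k; c >= 1; --c) {
    int i = cut[c][j];
    for (int t = i; t < j; ++t) lab[t] = c;
    j = i;
  }
  return lab;
}

// 8-connected component labelling of a logical mask (BFS flood fill).
// Returns an integer raster, 0 = background, components numbered in
// raster scan order of their first pixel.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push({i, j});
      while (!q.empty()) {
        auto [ci, cj] = q.front();
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = ci + di, jj = cj + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push({ii, jj});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Local mean over a square window (edge replication), via running sums.
// [[Rcpp::export(name = ".box_mean_cpp")]]
NumericMatrix box_mean_cpp(const NumericMatrix& x, const int window) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = window / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          s += x(ii, jj);
        }
      }
      out(i, j) = s / (double)(window * window);
    }
  }
  return out;
}
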