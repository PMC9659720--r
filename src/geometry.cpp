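#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Membership of 2D points in a convex polygon with counterclockwise vertices.
// A point is inside when it lies on the interior side of (or on) every edge;
// tol is an absolute tolerance on the signed point-to-edge distance, so
// boundary points count as inside.
// [[Rcpp::export]]
LogicalVector cpp_in_hull(NumericMatrix pts, NumericMatrix vert, double tol) {
  const int n = pts.nrow(), m = vert.nrow();
  std::vector<double> ex(m), ey(m), len(m);
  for (int k = 0; k < m; ++k) {
    int k2 = (k + 1) % m;
    ex[k] = vert(k2, 0) - vert(k, 0);
    ey[k] = vert(k2, 1) - vert(k, 1);
    len[k] = std::sqrt(ex[k] * ex[k] + ey[k] * ey[k]);
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1);
    bool inside = true;
    for (int k = 0; k < m; ++k) {
      double cr = ex[k] * (py - vert(k, 1)) - ey[k] * (px - vert(k, 0));
      if (cr < -tol * len[k]) { inside = false; break; }
    }
    out[i] = inside;
  }
  return out;
}

typedef std::map<std::pair<int, int>, std::vector<int> > CellMap;

static CellMap build_grid(const NumericMatrix& pts, double eps) {
  CellMap grid;
  const int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(pts(i, 0) / eps);
    int iy = (int)std::floor(pts(i, 1) / eps);
    grid[std::make_pair(ix, iy)].push_back(i);
  }
  return grid;
}

// DBSCAN noise detection in 2D. A point is retained when it belongs to some
// density cluster: either it is a core point (>= min_samples neighbours
// within eps, counting itself) or it has a core point within eps (border
// point). Grid binning with cell width eps keeps neighbour search local.
// [[Rcpp::export]]
LogicalVector cpp_dbscan_retain(NumericMatrix pts, double eps, int min_samples) {
  const int n = pts.nrow();
  const double eps2 = eps * eps;
  CellMap grid = build_grid(pts, eps);

  std::vector<bool> core(n, false);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(pts(i, 0) / eps);
    int iy = (int)std::floor(pts(i, 1) / eps);
    int cnt = 0;
    for (int dx = -1; dx <= 1 && cnt < min_samples; ++dx) {
      for (int dy = -1; dy <= 1 && cnt < min_samples; ++dy) {
        CellMap::const_iterator it = grid.find(std::make_pair(ix + dx, iy + dy));
        if (it == grid.end()) continue;
        const std::vector<int>& cell = it->second;
        for (size_t c = 0; c < cell.size(); ++c) {
          int j = cell[c];
          double ddx = pts(i, 0) - pts(j, 0), ddy = pts(i, 1) - pts(j, 1);
          if (ddx * ddx + ddy * ddy <= eps2) {
            if (++cnt >= min_samples) break;
          }
        }
      }
    }
    core[i] = (cnt >= min_samples);
  }

  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    if (core[i]) { out[i] = true; continue; }
    int ix = (int)std::floor(pts(i, 0) / eps);
    int iy = (int)std::floor(pts(i, 1) / eps);
    bool near_core = false;
    for (int dx = -1; dx <= 1 && !near_core; ++dx) {
      for (int dy = -1; dy <= 1 && !near_core; ++dy) {
        CellMap::const_iterator it = grid.find(std::make_pair(ix + dx, iy + dy));
        if (it == grid.end()) continue;
        const std::vector<int>& cell = it->second;
        for (size_t c = 0; c < cell.size(); ++c) {
          int j = cell[c];
          if (!core[j]) continue;
          double ddx = pts(i, 0) - pts(j, 0), ddy = pts(i, 1) - pts(j, 1);
          if (ddx * ddx + ddy * ddy <= eps2) { near_core = true; break; }
        }
      }
    }
    out[i] = near_core;
  }
  return out;
}

// Distance to the k-th nearest neighbour (self excluded) for every point.
// [[Rcpp::export]]
NumericVector cpp_knn_dist(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  NumericVector out(n);
  if (n <= 1) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  int kk = std::min(k, n - 1);
  std::vector<double> d2(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1);
      d2[m++] = dx * dx + dy * dy;
    }
    std::nth_element(d2.begin(), d2.begin() + (kk - 1), d2.end());
    out[i] = std::sqrt(d2[kk - 1]);
  }
  return out;
}
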