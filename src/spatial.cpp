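// Grid-hashed neighborhood primitives shared by row segmentation, trunk
// detection and outlier filtering. All distances are Euclidean, all grids
// are uniform with cell size equal to the query radius so a 3^D cell
// stencil is sufficient.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Grid {
  // linear cell index -> point indices
  std::unordered_map<long long, std::vector<int> > cells;
  double cell;
  double mn[3];
  long long nx, ny, nz;
  int dim;

  Grid(const NumericMatrix& pts, double cell_, int dim_) : cell(cell_), dim(dim_) {
    const int n = pts.nrow();
    double mx[3];
    for (int d = 0; d < dim; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < dim; ++d) {
        const double v = pts(i, d);
        if (v < mn[d]) mn[d] = v;
        if (v > mx[d]) mx[d] = v;
      }
    nx = ny = nz = 1;
    if (n > 0) {
      nx = (long long)std::floor((mx[0] - mn[0]) / cell) + 1;
      ny = (long long)std::floor((mx[1] - mn[1]) / cell) + 1;
      if (dim == 3) nz = (long long)std::floor((mx[2] - mn[2]) / cell) + 1;
    }
    cells.reserve(n);
    for (int i = 0; i < n; ++i) cells[key_of(pts, i)].push_back(i);
  }

  long long key(long long ix, long long iy, long long iz) const {
    return ix + nx * (iy + ny * iz);
  }

  long long key_of(const NumericMatrix& pts, int i) const {
    long long ix = (long long)std::floor((pts(i, 0) - mn[0]) / cell);
    long long iy = (long long)std::floor((pts(i, 1) - mn[1]) / cell);
    long long iz = dim == 3 ? (long long)std::floor((pts(i, 2) - mn[2]) / cell) : 0;
    return key(ix, iy, iz);
  }

  // indices of points within `radius` of point/query q (self included)
  void query(const NumericMatrix& pts, const double* q, double radius,
             std::vector<int>& out) const {
    out.clear();
    const double r2 = radius * radius;
    long long ix = (long long)std::floor((q[0] - mn[0]) / cell);
    long long iy = (long long)std::floor((q[1] - mn[1]) / cell);
    long long iz = dim == 3 ? (long long)std::floor((q[2] - mn[2]) / cell) : 0;
    const long long zlo = dim == 3 ? iz - 1 : 0, zhi = dim == 3 ? iz + 1 : 0;
    for (long long cz = zlo; cz <= zhi; ++cz)
      for (long long cy = iy - 1; cy <= iy + 1; ++cy)
        for (long long cx = ix - 1; cx <= ix + 1; ++cx) {
          auto it = cells.find(key(cx, cy, cz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            double d2 = 0.0;
            for (int d = 0; d < dim; ++d) {
              const double dd = pts(j, d) - q[d];
              d2 += dd * dd;
            }
            if (d2 <= r2) out.push_back(j);
          }
        }
  }
};

// Jacobi eigenvalues of a symmetric 3x3, descending order.
void eigen3_sym(double a[3][3], double ev[3]) {
  double v;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-30) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-30) continue;
        const double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        const double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          const double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          const double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
      }
  }
  ev[0] = a[0][0]; ev[1] = a[1][1]; ev[2] = a[2][2];
  if (ev[0] < ev[1]) { v = ev[0]; ev[0] = ev[1]; ev[1] = v; }
  if (ev[1] < ev[2]) { v = ev[1]; ev[1] = ev[2]; ev[2] = v; }
  if (ev[0] < ev[1]) { v = ev[0]; ev[0] = ev[1]; ev[1] = v; }
}

} // namespace

// [[Rcpp::export(name = ".dbscan_cpp")]]
IntegerVector dbscan_cpp(NumericMatrix pts, double eps, int min_pts) {
  const int n = pts.nrow();
  const int dim = pts.ncol();
  IntegerVector labels(n, -2); // -2 unvisited, -1 noise, >=0 cluster
  if (n == 0) return labels;
  Grid grid(pts, eps, dim);
  std::vector<int> nb, nb2;
  double q[3];
  int cluster = 0;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != -2) continue;
    for (int d = 0; d < dim; ++d) q[d] = pts(i, d);
    grid.query(pts, q, eps, nb);
    if ((int)nb.size() < min_pts) { labels[i] = -1; continue; }
    labels[i] = cluster;
    std::queue<int> todo;
    for (int j : nb) if (j != i) todo.push(j);
    while (!todo.empty()) {
      const int j = todo.front(); todo.pop();
      if (labels[j] == -1) labels[j] = cluster;      // border point
      if (labels[j] != -2) continue;
      labels[j] = cluster;
      for (int d = 0; d < dim; ++d) q[d] = pts(j, d);
      grid.query(pts, q, eps, nb2);
      if ((int)nb2.size() >= min_pts)
        for (int k : nb2) if (labels[k] == -2 || labels[k] == -1) todo.push(k);
    }
    ++cluster;
  }
  return labels;
}

// Per-point covariance eigenvalues and sphericity within radius R.
// Returns N x 4 matrix: lambda1 >= lambda2 >= lambda3, sphericity.
// [[Rcpp::export(name = ".sphericity_cpp")]]
NumericMatrix sphericity_cpp(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  NumericMatrix out(n, 4);
  if (n == 0) return out;
  Grid grid(pts, radius, 3);
  std::vector<int> nb;
  double q[3];
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) q[d] = pts(i, d);
    grid.query(pts, q, radius, nb);
    const int m = (int)nb.size();
    if (m < 3) continue; // eigenvalues and sphericity stay 0
    double mean[3] = {0, 0, 0};
    for (int j : nb)
      for (int d = 0; d < 3; ++d) mean[d] += pts(j, d);
    for (int d = 0; d < 3; ++d) mean[d] /= m;
    double c[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j : nb) {
      double dv[3];
      for (int d = 0; d < 3; ++d) dv[d] = pts(j, d) - mean[d];
      for (int r = 0; r < 3; ++r)
        for (int s = r; s < 3; ++s) c[r][s] += dv[r] * dv[s];
    }
    for (int r = 0; r < 3; ++r)
      for (int s = r; s < 3; ++s) { c[r][s] /= m; c[s][r] = c[r][s]; }
    double ev[3];
    eigen3_sym(c, ev);
    for (int d = 0; d < 3; ++d) if (ev[d] < 0) ev[d] = 0;
    out(i, 0) = ev[0]; out(i, 1) = ev[1]; out(i, 2) = ev[2];
    out(i, 3) = ev[0] > 0 ? ev[2] / ev[0] : 0.0;
    if (out(i, 3) > 1.0) out(i, 3) = 1.0;
  }
  return out;
}

// Mean distance of each point to its k nearest neighbours (self excluded),
// by ring expansion over a uniform grid.
// [[Rcpp::export(name = ".knn_meandist_cpp")]]
NumericVector knn_meandist_cpp(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  NumericVector out(n);
  if (n == 0) return out;
  // heuristic cell size: expected k-neighbour radius for a uniform cloud
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (pts(i, d) < mn[d]) mn[d] = pts(i, d);
      if (pts(i, d) > mx[d]) mx[d] = pts(i, d);
    }
  double vol = 1.0, span = 0.0;
  for (int d = 0; d < 3; ++d) {
    const double e = std::max(mx[d] - mn[d], 1e-9);
    vol *= e;
    span = std::max(span, e);
  }
  double cell = std::cbrt(vol * (k + 1) / n);
  if (!(cell > 0) || cell > span) cell = span;
  Grid grid(pts, cell, 3);
  std::vector<std::pair<double, int> > cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    long long ix = (long long)std::floor((pts(i, 0) - grid.mn[0]) / cell);
    long long iy = (long long)std::floor((pts(i, 1) - grid.mn[1]) / cell);
    long long iz = (long long)std::floor((pts(i, 2) - grid.mn[2]) / cell);
    double kth = R_PosInf;
    const long long max_ring =
        std::max(grid.nx, std::max(grid.ny, grid.nz));
    for (long long ring = 0; ring <= max_ring; ++ring) {
      // once enough candidates collected, a further ring cannot beat kth
      if ((int)cand.size() >= k && (double)(ring - 1) * cell > kth) break;
      for (long long cz = iz - ring; cz <= iz + ring; ++cz)
        for (long long cy = iy - ring; cy <= iy + ring; ++cy)
          for (long long cx = ix - ring; cx <= ix + ring; ++cx) {
            if (std::max(std::llabs(cx - ix),
                         std::max(std::llabs(cy - iy), std::llabs(cz - iz))) != ring)
              continue;
            auto it = grid.cells.find(grid.key(cx, cy, cz));
            if (it == grid.cells.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              double d2 = 0.0;
              for (int d = 0; d < 3; ++d) {
                const double dd = pts(j, d) - pts(i, d);
                d2 += dd * dd;
              }
              cand.push_back(std::make_pair(std::sqrt(d2), j));
            }
          }
      if ((int)cand.size() >= k) {
        std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
        kth = cand[k - 1].first;
      }
    }
    const int kk = std::min(k, (int)cand.size());
    if (kk == 0) { out[i] = NA_REAL; continue; }
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    double s = 0.0;
    for (int j = 0; j < kk; ++j) s += cand[j].first;
    out[i] = s / kk;
  }
  return out;
}

// For each 2D query point, the label of the nearest labelled reference
// point within max_dist, else -1. Used to attach full-resolution points
// whose voxel representative fell out as DBSCAN noise.
// [[Rcpp::export(name = ".nearest_label_cpp")]]
IntegerVector nearest_label_cpp(NumericMatrix query, NumericMatrix ref,
                                IntegerVector labels, double max_dist) {
  const int m = query.nrow();
  IntegerVector out(m, -1);
  if (m == 0 || ref.nrow() == 0) return out;
  Grid grid(ref, max_dist, 2);
  std::vector<int> nb;
  double q[2];
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1);
    grid.query(ref, q, max_dist, nb);
    double best = R_PosInf;
    for (int j : nb) {
      if (labels[j] < 0) continue;
      const double dx = ref(j, 0) - q[0], dy = ref(j, 1) - q[1];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; out[i] = labels[j]; }
    }
  }
  return out;
}
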