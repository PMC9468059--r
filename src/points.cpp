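#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Nearest-neighbour distances for a 3-D point set (um), via a uniform-grid
// spatial index with expanding-ring search.  Exactness against the all-pairs
// brute force is asserted by the test suite.

static inline long long cellkey(int cx, int cy, int cz) {
  return ((long long)(cx + 1048576) << 42) |
         ((long long)(cy + 1048576) << 21) |
         (long long)(cz + 1048576);
}

// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector out(n);
  if (n < 2) stop("need at least 2 points");
  if (n <= 64) { // brute force for tiny sets
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::infinity();
      for (int j = 0; j < n; ++j) {
        if (i == j) continue;
        double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1), dz = pts(i, 2) - pts(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
      out[i] = std::sqrt(best);
    }
    return out;
  }
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = hi[k] = pts(0, k);
    for (int i = 1; i < n; ++i) {
      lo[k] = std::min(lo[k], pts(i, k));
      hi[k] = std::max(hi[k], pts(i, k));
    }
  }
  double vol = 1.0;
  for (int k = 0; k < 3; ++k) vol *= std::max(hi[k] - lo[k], 1e-9);
  double h = std::cbrt(vol / n);
  if (!(h > 0) || !std::isfinite(h)) h = 1.0;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(2 * n);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    ci[i] = (int)std::floor((pts(i, 0) - lo[0]) / h);
    cj[i] = (int)std::floor((pts(i, 1) - lo[1]) / h);
    ck[i] = (int)std::floor((pts(i, 2) - lo[2]) / h);
    grid[cellkey(ci[i], cj[i], ck[i])].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int ring = 0;; ++ring) {
      for (int ax = -ring; ax <= ring; ++ax)
        for (int ay = -ring; ay <= ring; ++ay)
          for (int az = -ring; az <= ring; ++az) {
            if (std::max(std::abs(ax), std::max(std::abs(ay), std::abs(az))) != ring) continue;
            std::unordered_map<long long, std::vector<int> >::const_iterator it =
              grid.find(cellkey(ci[i] + ax, cj[i] + ay, ck[i] + az));
            if (it == grid.end()) continue;
            for (size_t t = 0; t < it->second.size(); ++t) {
              int j = it->second[t];
              if (j == i) continue;
              double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1), dz = pts(i, 2) - pts(j, 2);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) best = d2;
            }
          }
      // any point beyond ring `ring` is at distance >= ring*h from pts[i]
      if (best <= (double)ring * h * (double)ring * h) break;
      if (ring > 4 && std::isfinite(best)) {
        // safety: cannot improve beyond sqrt(best)/h more rings
        if ((double)(ring)*h > std::sqrt(best)) break;
      }
      if (ring > 1000000) stop("nn search failed to terminate");
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Minimum distance (um) from each listed voxel centre to any of the supplied
// points.  fg_idx are 1-based linear indices into an array of dim (nz,ny,nx).
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_points(IntegerVector fg_idx, IntegerVector dim,
                                     NumericVector voxel, NumericMatrix pts) {
  const int nz = dim[0], ny = dim[1];
  const double dzs = voxel[0], dys = voxel[1], dxs = voxel[2];
  const int m = fg_idx.size(), k = pts.nrow();
  if (k < 1) stop("need at least one point");
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    R_xlen_t i = (R_xlen_t)fg_idx[t] - 1;
    int z = (int)(i % nz);
    R_xlen_t r = i / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    double px = x * dxs, py = y * dys, pz = z * dzs;
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < k; ++j) {
      double dx = px - pts(j, 0), dy = py - pts(j, 1), dz = pz - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[t] = std::sqrt(best);
  }
  return out;
}
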