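#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Shared indexing: R array [z,y,x], dim = (nz,ny,nx), 0-based linear
// i = z + nz*(y + ny*x).

struct Grid {
  int nz, ny, nx;
  R_xlen_t n;
  Grid(IntegerVector dim) : nz(dim[0]), ny(dim[1]), nx(dim[2]) {
    n = (R_xlen_t)nz * ny * nx;
  }
  inline R_xlen_t idx(int z, int y, int x) const {
    return z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
  }
  inline void coords(R_xlen_t i, int &z, int &y, int &x) const {
    z = (int)(i % nz);
    R_xlen_t r = i / nz;
    y = (int)(r % ny);
    x = (int)(r / ny);
  }
};

// 26- or 6-connected component labelling of a binary mask.
// Returns integer labels (0 background) with component sizes as attribute.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  IntegerVector lab(g.n, 0);
  std::vector<double> sizes;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    double sz = 0;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      ++sz;
      int z, y, x;
      g.coords(c, z, y, x);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            if (connectivity == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) != 1) continue;
            int z2 = z + dz, y2 = y + dy, x2 = x + dx;
            if (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= g.nz || y2 >= g.ny || x2 >= g.nx) continue;
            R_xlen_t j = g.idx(z2, y2, x2);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
    sizes.push_back(sz);
  }
  lab.attr("sizes") = wrap(sizes);
  return lab;
}

// Fill interior cavities: background voxels not 6-connected to the grid
// boundary become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<char> outside(g.n, 0);
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y)
      for (int z = 0; z < g.nz; ++z) {
        bool border = (x == 0 || y == 0 || z == 0 || x == g.nx - 1 || y == g.ny - 1 || z == g.nz - 1);
        if (!border) continue;
        R_xlen_t i = g.idx(z, y, x);
        if (!mask[i] && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
  const int dzs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t c = stack.back();
    stack.pop_back();
    int z, y, x;
    g.coords(c, z, y, x);
    for (int k = 0; k < 6; ++k) {
      int z2 = z + dzs[k], y2 = y + dys[k], x2 = x + dxs[k];
      if (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= g.nz || y2 >= g.ny || x2 >= g.nx) continue;
      R_xlen_t j = g.idx(z2, y2, x2);
      if (!mask[j] && !outside[j]) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  LogicalVector out(g.n);
  for (R_xlen_t i = 0; i < g.n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Running min/max filter with half-window r (voxels) along one axis
// (0 = z, 1 = y, 2 = x).  Used for grayscale box erosion/dilation (top-hat).
// [[Rcpp::export]]
NumericVector cpp_minmax_axis(NumericVector img, IntegerVector dim, int axis, int r, bool do_max) {
  Grid g(dim);
  NumericVector out(g.n);
  int len = (axis == 0) ? g.nz : (axis == 1) ? g.ny : g.nx;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)g.nz : (R_xlen_t)g.nz * g.ny;
  // iterate over all lines along `axis`
  int nA = (axis == 0) ? g.ny : g.nz;
  int nB = (axis == 0) ? g.nx : (axis == 1) ? g.nx : g.ny;
  std::vector<double> line(len);
  for (int b = 0; b < nB; ++b)
    for (int a = 0; a < nA; ++a) {
      R_xlen_t base;
      if (axis == 0) base = g.idx(0, a, b);
      else if (axis == 1) base = g.idx(a, 0, b);
      else base = g.idx(a, b, 0);
      for (int q = 0; q < len; ++q) line[q] = img[base + stride * q];
      for (int q = 0; q < len; ++q) {
        int lo = std::max(0, q - r), hi = std::min(len - 1, q + r);
        double v = line[lo];
        for (int t = lo + 1; t <= hi; ++t)
          v = do_max ? std::max(v, line[t]) : std::min(v, line[t]);
        out[base + stride * q] = v;
      }
    }
  return out;
}

// Separable Gaussian smoothing along one axis, reflecting boundaries.
// [[Rcpp::export]]
NumericVector cpp_gauss_axis(NumericVector img, IntegerVector dim, int axis, double sigma_vox) {
  Grid g(dim);
  int rad = (int)std::ceil(3.0 * sigma_vox);
  if (rad < 1) return clone(img);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma_vox * sigma_vox));
    s += ker[t + rad];
  }
  for (double &k : ker) k /= s;
  NumericVector out(g.n);
  int len = (axis == 0) ? g.nz : (axis == 1) ? g.ny : g.nx;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)g.nz : (R_xlen_t)g.nz * g.ny;
  int nA = (axis == 0) ? g.ny : g.nz;
  int nB = (axis == 0) ? g.nx : (axis == 1) ? g.nx : g.ny;
  std::vector<double> line(len);
  for (int b = 0; b < nB; ++b)
    for (int a = 0; a < nA; ++a) {
      R_xlen_t base;
      if (axis == 0) base = g.idx(0, a, b);
      else if (axis == 1) base = g.idx(a, 0, b);
      else base = g.idx(a, b, 0);
      for (int q = 0; q < len; ++q) line[q] = img[base + stride * q];
      for (int q = 0; q < len; ++q) {
        double acc = 0;
        for (int t = -rad; t <= rad; ++t) {
          int p = q + t;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= len) p = 2 * len - p - 1;
          if (p < 0) p = 0;                 // degenerate short lines
          if (p >= len) p = len - 1;
          acc += ker[t + rad] * line[p];
        }
        out[base + stride * q] = acc;
      }
    }
  return out;
}

// 26-neighbourhood local maxima strictly above hmin ( >= all neighbours ).
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector img, IntegerVector dim, double hmin) {
  Grid g(dim);
  LogicalVector out(g.n, 0);
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y)
      for (int z = 0; z < g.nz; ++z) {
        R_xlen_t i = g.idx(z, y, x);
        double v = img[i];
        if (!(v > hmin)) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dz && !dy && !dx) continue;
              int z2 = z + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= g.nz || y2 >= g.ny || x2 >= g.nx) continue;
              if (img[g.idx(z2, y2, x2)] > v) { ismax = false; break; }
            }
        if (ismax) out[i] = 1;
      }
  return out;
}

// Seeded watershed by priority flooding (Meyer).  Floods the mask from the
// labelled seeds in order of increasing `priority` (pass -distance to flood
// ridges last).  26-connected.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, LogicalVector mask,
                            IntegerVector seeds, IntegerVector dim) {
  Grid g(dim);
  IntegerVector lab(g.n, 0);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(Node(priority[i], i));
    }
  }
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    R_xlen_t c = nd.second;
    int z, y, x;
    g.coords(c, z, y, x);
    int L = lab[c];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z2 = z + dz, y2 = y + dy, x2 = x + dx;
          if (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= g.nz || y2 >= g.ny || x2 >= g.nx) continue;
          R_xlen_t j = g.idx(z2, y2, x2);
          if (mask[j] && !lab[j]) {
            lab[j] = L;
            pq.push(Node(std::max(nd.first, priority[j]), j));
          }
        }
  }
  return lab;
}

// Per-voxel count of foreground voxels among the 26 neighbours.
// [[Rcpp::export]]
IntegerVector cpp_count_neighbors26(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  IntegerVector out(g.n, 0);
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y)
      for (int z = 0; z < g.nz; ++z) {
        R_xlen_t i = g.idx(z, y, x);
        if (!mask[i]) continue;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dz && !dy && !dx) continue;
              int z2 = z + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= g.nz || y2 >= g.ny || x2 >= g.nx) continue;
              if (mask[g.idx(z2, y2, x2)]) ++cnt;
            }
        out[i] = cnt;
      }
  return out;
}
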