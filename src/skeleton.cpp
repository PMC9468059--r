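#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Curve-skeleton extraction by iterative removal of simple border points
// (topology-preserving thinning).  A voxel is "simple" when deleting it
// changes neither the number of 26-connected foreground components in its
// 3x3x3 neighbourhood nor the number of 6-connected background components
// 6-adjacent to it (Malandain & Bertrand characterization).  Endpoints
// (<= 1 foreground neighbour) are retained so curve ends survive.  Six
// directional sub-iterations give an approximately medial result; adequacy
// for branch counting on tubular structures is asserted by tests.

static inline int off(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1)); // 0..26, centre = 13
}

// 26-connectivity of the foreground within N26 (centre excluded).
static bool one_fg_component26(const bool nb[27]) {
  int comp[27];
  for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp = 0;
  int stack[27], top;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || comp[i] >= 0) continue;
    comp[i] = ncomp;
    top = 0;
    stack[top++] = i;
    while (top) {
      int c = stack[--top];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
            if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
            int j = z2 + 3 * (y2 + 3 * x2);
            if (j == 13 || j == c || !nb[j] || comp[j] >= 0) continue;
            comp[j] = ncomp;
            stack[top++] = j;
          }
    }
    ++ncomp;
  }
  return ncomp == 1;
}

// 6-connected background components within N18 that touch a 6-neighbour of
// the centre; must be exactly one.
static bool one_bg_component6(const bool nb[27]) {
  bool in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        in18[off(dz, dy, dx)] = (manh >= 1 && manh <= 2);
      }
  int comp[27];
  for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp_touching = 0;
  int stack[27], top;
  int seen = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || comp[i] >= 0) continue;
    // flood this background component within N18 (6-adjacency)
    bool touches = false;
    comp[i] = seen;
    top = 0;
    stack[top++] = i;
    while (top) {
      int c = stack[--top];
      int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
      if (std::abs(cz) + std::abs(cy) + std::abs(cx) == 1) touches = true;
      const int dzs[6] = {1, -1, 0, 0, 0, 0};
      const int dys[6] = {0, 0, 1, -1, 0, 0};
      const int dxs[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; ++k) {
        int z2 = cz + dzs[k], y2 = cy + dys[k], x2 = cx + dxs[k];
        if (z2 < -1 || z2 > 1 || y2 < -1 || y2 > 1 || x2 < -1 || x2 > 1) continue;
        int j = off(z2, y2, x2);
        if (!in18[j] || nb[j] || comp[j] >= 0) continue;
        comp[j] = seen;
        stack[top++] = j;
      }
    }
    if (touches) ++ncomp_touching;
    ++seen;
  }
  return ncomp_touching == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  const int dzs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, -1, 1};

  bool nb[27];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
            if (!m[i]) continue;
            int z2 = z + dzs[dir], y2 = y + dys[dir], x2 = x + dxs[dir];
            bool bg = (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= nz || y2 >= ny || x2 >= nx) ||
                      !m[z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2)];
            if (bg) cand.push_back(i);
          }
      for (size_t t = 0; t < cand.size(); ++t) {
        R_xlen_t i = cand[t];
        if (!m[i]) continue;
        int z = (int)(i % nz);
        R_xlen_t r = i / nz;
        int y = (int)(r % ny);
        int x = (int)(r / ny);
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int zz = z + dz, yy = y + dy, xx = x + dx;
              bool fg = !(zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx) &&
                        m[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
              nb[off(dz, dy, dx)] = fg;
              if (fg && !(dz == 0 && dy == 0 && dx == 0)) ++cnt;
            }
        if (cnt <= 1) continue; // endpoint (or isolated): keep
        if (one_fg_component26(nb) && one_bg_component6(nb)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}
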