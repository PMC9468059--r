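#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Arrays are R arrays indexed [z, y, x]; dim = (nz, ny, nx); the first index
// varies fastest.  voxel = (dz, dy, dx) in micrometres.  Linear 0-based index
// i = z + nz * (y + ny * x).

// "no source on this line yet": finite so parabola arithmetic stays well
// defined; far larger than any attainable squared distance (grids are < 1e5 um).
static const double BIG = 1e30;

// 1-D squared-distance transform (lower envelope of parabolas) with squared
// physical spacing w2 per index step (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double val = f[p] + w2 * (q - p) * (q - p);
    d[q] = val;
  }
}

// Squared Euclidean distance (um^2) from every voxel centre to the nearest
// source voxel centre.  Exact, separable, anisotropic.  Voxels with no source
// anywhere get a value >= BIG (callers treat those as "infinitely far").
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector source, IntegerVector dim, NumericVector voxel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = source[i] ? 0.0 : BIG;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), g(nmax), z(nmax + 2);
  std::vector<int> v(nmax);

  double w2 = voxel[0] * voxel[0]; // along z, stride 1
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; ++q) f[q] = d[base + q];
      dt1d(f, g, v, z, nz, w2);
      for (int q = 0; q < nz; ++q) d[base + q] = g[q];
    }
  w2 = voxel[1] * voxel[1]; // along y, stride nz
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; ++q) f[q] = d[base + (R_xlen_t)nz * q];
      dt1d(f, g, v, z, ny, w2);
      for (int q = 0; q < ny; ++q) d[base + (R_xlen_t)nz * q] = g[q];
    }
  w2 = voxel[2] * voxel[2]; // along x, stride nz*ny
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * y;
      for (int q = 0; q < nx; ++q) f[q] = d[base + sx * q];
      dt1d(f, g, v, z, nx, w2);
      for (int q = 0; q < nx; ++q) d[base + sx * q] = g[q];
    }
  return d;
}
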