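#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel painting for the phantom generator.  Coordinates are physical um with
// the origin at the centre of voxel (0,0,0); point order is (x, y, z) while
// arrays are [z, y, x] with dim = (nz, ny, nx) and voxel = (dz, dy, dx).
// `img` is modified in place (set to max(img, value)); `owner` records the
// first compartment that claimed each voxel (0 = unclaimed).  The return
// value is the number of voxels newly claimed for `owner_code`.

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
}

static void frame_from_axis(const double *u_in, double *u, double *v, double *w) {
  double nrm = std::sqrt(u_in[0] * u_in[0] + u_in[1] * u_in[1] + u_in[2] * u_in[2]);
  if (nrm < 1e-12) { u[0] = 1; u[1] = 0; u[2] = 0; }
  else { u[0] = u_in[0] / nrm; u[1] = u_in[1] / nrm; u[2] = u_in[2] / nrm; }
  // any vector not parallel to u
  double a[3] = {0, 0, 1};
  if (std::fabs(u[2]) > 0.9) { a[0] = 1; a[2] = 0; }
  // v = normalize(a x u), w = u x v
  v[0] = a[1] * u[2] - a[2] * u[1];
  v[1] = a[2] * u[0] - a[0] * u[2];
  v[2] = a[0] * u[1] - a[1] * u[0];
  double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= nv; v[1] /= nv; v[2] /= nv;
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}

// [[Rcpp::export]]
int cpp_paint_ellipsoid(NumericVector img, IntegerVector owner, IntegerVector dim,
                        NumericVector voxel, NumericVector center_xyz,
                        NumericVector semi_axes, NumericVector axis_xyz,
                        double value, int owner_code) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = voxel[0], dy = voxel[1], dx = voxel[2];
  double u[3], v[3], w[3];
  frame_from_axis(REAL(axis_xyz), u, v, w);
  const double a = semi_axes[0], b = semi_axes[1], c = semi_axes[2];
  const double rmax = std::max(a, std::max(b, c));
  const double cx = center_xyz[0], cy = center_xyz[1], cz = center_xyz[2];
  int x0 = std::max(0, (int)std::floor((cx - rmax) / dx));
  int x1 = std::min(nx - 1, (int)std::ceil((cx + rmax) / dx));
  int y0 = std::max(0, (int)std::floor((cy - rmax) / dy));
  int y1 = std::min(ny - 1, (int)std::ceil((cy + rmax) / dy));
  int z0 = std::max(0, (int)std::floor((cz - rmax) / dz));
  int z1 = std::min(nz - 1, (int)std::ceil((cz + rmax) / dz));
  int painted = 0;
  for (int x = x0; x <= x1; ++x) {
    double px = x * dx - cx;
    for (int y = y0; y <= y1; ++y) {
      double py = y * dy - cy;
      for (int z = z0; z <= z1; ++z) {
        double pz = z * dz - cz;
        double qu = (px * u[0] + py * u[1] + pz * u[2]) / a;
        double qv = (px * v[0] + py * v[1] + pz * v[2]) / b;
        double qw = (px * w[0] + py * w[1] + pz * w[2]) / c;
        if (qu * qu + qv * qv + qw * qw <= 1.0) {
          R_xlen_t i = lin(z, y, x, nz, ny);
          if (img[i] < value) img[i] = value;
          if (owner[i] == 0) { owner[i] = owner_code; ++painted; }
        }
      }
    }
  }
  return painted;
}

// Paint voxels within `radius` of the segment p0-p1 (a capsule).
// [[Rcpp::export]]
int cpp_paint_capsule(NumericVector img, IntegerVector owner, IntegerVector dim,
                      NumericVector voxel, NumericVector p0, NumericVector p1,
                      double radius, double value, int owner_code) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = voxel[0], dy = voxel[1], dx = voxel[2];
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = std::min(p0[k], p1[k]) - radius;
    hi[k] = std::max(p0[k], p1[k]) + radius;
  }
  int x0 = std::max(0, (int)std::floor(lo[0] / dx));
  int x1 = std::min(nx - 1, (int)std::ceil(hi[0] / dx));
  int y0 = std::max(0, (int)std::floor(lo[1] / dy));
  int y1 = std::min(ny - 1, (int)std::ceil(hi[1] / dy));
  int z0 = std::max(0, (int)std::floor(lo[2] / dz));
  int z1 = std::min(nz - 1, (int)std::ceil(hi[2] / dz));
  double ax = p1[0] - p0[0], ay = p1[1] - p0[1], az = p1[2] - p0[2];
  double len2 = ax * ax + ay * ay + az * az;
  double r2 = radius * radius;
  int painted = 0;
  for (int x = x0; x <= x1; ++x) {
    double px = x * dx - p0[0];
    for (int y = y0; y <= y1; ++y) {
      double py = y * dy - p0[1];
      for (int z = z0; z <= z1; ++z) {
        double pz = z * dz - p0[2];
        double t = (len2 > 0) ? (px * ax + py * ay + pz * az) / len2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double ex = px - t * ax, ey = py - t * ay, ez = pz - t * az;
        if (ex * ex + ey * ey + ez * ez <= r2) {
          R_xlen_t i = lin(z, y, x, nz, ny);
          if (img[i] < value) img[i] = value;
          if (owner[i] == 0) { owner[i] = owner_code; ++painted; }
        }
      }
    }
  }
  return painted;
}
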