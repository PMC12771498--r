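#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// sample locations i * s for grid spacing s in mm.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sp;
    while (true) {
      double xv = v[k] * s;
      sp = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sp <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sp;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest set voxel
// of a binary 3-D array on an anisotropic regular grid. Set voxels get 0.
// Unset voxels start at a large finite sentinel (not Inf, which poisons the
// parabola intersections with NaN); an all-zero mask returns the sentinel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double LARGE = 1e15;
  NumericVector D(nx * ny * nz);
  for (int i = 0; i < mask.size(); ++i) D[i] = mask[i] ? 0.0 : LARGE;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x (fastest-varying index)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = D[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = D[base + z * nxy];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) D[base + z * nxy] = d[z];
    }
  return D;
}

// Binary dilation of a 3-D mask by an explicit list of integer voxel offsets
// (n x 3, includes the zero offset for output >= input). Offsets falling
// outside the array are clipped.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  LogicalVector out(mask.size());
  const int noff = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = z * nxy + (R_xlen_t)y * nx + x;
        if (!mask[idx]) continue;
        for (int o = 0; o < noff; ++o) {
          int xx = x + offsets(o, 0);
          int yy = y + offsets(o, 1);
          int zz = z + offsets(o, 2);
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          out[zz * nxy + (R_xlen_t)yy * nx + xx] = true;
        }
      }
  return out;
}
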