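#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic grid, by the
// separable lower-envelope (parabola) method applied axis by axis.
// Parabola abscissae are physical positions i * s for axis spacing s,
// so the result is exact for arbitrary per-axis voxel sizes.

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform of sampled function f at spacing s.
// Only finite parabolas enter the lower envelope; a line with no finite
// entry transforms to all-infinite.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  int k = -1;
  const double s2 = s * s;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double sx;
    while (true) {
      const int p = v[k];
      sx = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sx <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = sx;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// mask: logical array, dim = c(nz, ny, nx), column-major (z fastest).
// spacing: (z, y, x) physical voxel sizes.
// Returns distances (same layout) from every voxel centre to the nearest
// TRUE voxel centre; TRUE voxels get 0.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  if (dims.size() != 3 || spacing.size() != 3)
    stop("dims and spacing must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  if (sz <= 0 || sy <= 0 || sx <= 0) stop("voxel sizes must be positive");

  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      const R_xlen_t base = (R_xlen_t)ix * ny * nz + (R_xlen_t)iy * nz;
      bool any = false;
      for (int iz = 0; iz < nz; ++iz) { f[iz] = g[base + iz]; if (f[iz] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, nz, sz);
      for (int iz = 0; iz < nz; ++iz) g[base + iz] = d[iz];
    }
  // pass along y (stride nz)
  for (int ix = 0; ix < nx; ++ix)
    for (int iz = 0; iz < nz; ++iz) {
      const R_xlen_t base = (R_xlen_t)ix * ny * nz + iz;
      bool any = false;
      for (int iy = 0; iy < ny; ++iy) { f[iy] = g[base + (R_xlen_t)iy * nz]; if (f[iy] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, ny, sy);
      for (int iy = 0; iy < ny; ++iy) g[base + (R_xlen_t)iy * nz] = d[iy];
    }
  // pass along x (stride ny*nz)
  const R_xlen_t sxstride = (R_xlen_t)ny * nz;
  for (int iy = 0; iy < ny; ++iy)
    for (int iz = 0; iz < nz; ++iz) {
      const R_xlen_t base = (R_xlen_t)iy * nz + iz;
      bool any = false;
      for (int ix = 0; ix < nx; ++ix) { f[ix] = g[base + (R_xlen_t)ix * sxstride]; if (f[ix] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, nx, sx);
      for (int ix = 0; ix < nx; ++ix) g[base + (R_xlen_t)ix * sxstride] = d[ix];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    g[i] = (g[i] == INF) ? INF : std::sqrt(g[i]);
  return g;
}
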