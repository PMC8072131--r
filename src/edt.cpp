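#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Separable squared Euclidean distance transform (lower envelope of
// parabolas), anisotropy-aware: each axis contributes (delta * spacing)^2.
// Exact: the result equals min over feature voxels of the squared
// anisotropic distance, computed in double arithmetic.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared DT of sampled function f (INF = no parabola); result in d
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s2) {
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    while (k >= 0) {
      int p = v[k];
      double s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
                 (2.0 * s2 * (q - p));
      if (s <= z[k]) k--; else { z[k + 1] = s; break; }
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { k++; v[k] = q; z[k + 1] = INF; }
  }
  if (k < 0) { for (int q = 0; q < n; q++) d[q] = INF; return; }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < q) j++;
    int p = v[j];
    d[q] = s2 * (double)(q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = feature[i] ? 0.0 : INF;
  double sx2 = spacing[0] * spacing[0];
  double sy2 = spacing[1] * spacing[1];
  double sz2 = spacing[2] * spacing[2];
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 2);
  std::vector<int> v(nmax);

  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int q = 0; q < nx; q++) f[q] = out[base + q];
      dt1d(f, d, v, z, nx, sx2);
      for (int q = 0; q < nx; q++) out[base + q] = d[q];
    }
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int q = 0; q < ny; q++) f[q] = out[base + (R_xlen_t)q * nx];
      dt1d(f, d, v, z, ny, sy2);
      for (int q = 0; q < ny; q++) out[base + (R_xlen_t)q * nx] = d[q];
    }
  R_xlen_t pz = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int q = 0; q < nz; q++) f[q] = out[base + (R_xlen_t)q * pz];
      dt1d(f, d, v, z, nz, sz2);
      for (int q = 0; q < nz; q++) out[base + (R_xlen_t)q * pz] = d[q];
    }
  return out;
}
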