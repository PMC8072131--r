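#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable 3D convolution with per-axis Gaussian kernels (reflect padding).
// sigma is given in voxels per axis; sigma <= 0 skips that axis.

static void conv_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, const std::vector<double>& ker) {
  int r = (int)(ker.size() / 2);
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
  std::vector<double> line(len);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int j2 = 0; j2 < n2; j2++)
    for (int j1 = 0; j1 < n1; j1++) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)j2 * nx * ny + (R_xlen_t)j1 * nx;
      else if (axis == 1) base = (R_xlen_t)j2 * nx * ny + j1;
      else base = (R_xlen_t)j2 * nx + j1;
      for (int q = 0; q < len; q++) line[q] = a[base + (R_xlen_t)q * stride];
      for (int q = 0; q < len; q++) {
        double acc = 0.0;
        for (int t = -r; t <= r; t++) {
          int p = q + t;
          if (p < 0) p = -p - 1;          // reflect
          if (p >= len) p = 2 * len - p - 1;
          acc += line[p] * ker[t + r];
        }
        a[base + (R_xlen_t)q * stride] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector x, IntegerVector dim,
                          NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; i++) a[i] = x[i];
  for (int axis = 0; axis < 3; axis++) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; t++) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (auto& k : ker) k /= sum;
    conv_axis(a, nx, ny, nz, axis, ker);
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = a[i];
  return out;
}
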