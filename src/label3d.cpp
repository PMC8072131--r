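#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D logical grid, 6- or 26-connectivity,
// iterative BFS (no recursion). Labels are assigned in scan order; callers
// re-order by size.

// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n); // zero-initialized
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int nOff = (int)offx.size();
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    cur++;
    lab[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int pz = (int)(p / ((R_xlen_t)nx * ny));
      int rem = (int)(p % ((R_xlen_t)nx * ny));
      int py = rem / nx, px = rem % nx;
      for (int j = 0; j < nOff; j++) {
        int qx = px + offx[j], qy = py + offy[j], qz = pz + offz[j];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)qz * nx * ny + (R_xlen_t)qy * nx + qx;
        if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}
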