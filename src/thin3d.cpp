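#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Topology-preserving 3D curve thinning. A border voxel is deleted when it
// is a simple point (removal leaves both the foreground 26-topology and the
// background 6-topology of its neighborhood unchanged) and not a curve
// endpoint. Deletion proceeds in six directional subiterations per round,
// re-testing simplicity at deletion time, until no voxel can be removed.
// The simple-point test is the local-neighborhood characterization of
// Bertrand & Malandain: exactly one 26-component of foreground in N26*, and
// exactly one 6-component of background within N18 that touches a face
// neighbor.

// neighborhood index: (dx+1) + 3*(dy+1) + 9*(dz+1), center = 13
static inline int nidx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static int fg_components26(const bool* nb) {
  // components of foreground among the 26 neighbors, 26-adjacency
  int comp[27];
  for (int i = 0; i < 27; i++) comp[i] = -1;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !nb[s] || comp[s] >= 0) continue;
    int top = 0;
    stack[top++] = s;
    comp[s] = ncomp;
    while (top > 0) {
      int p = stack[--top];
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      for (int q = 0; q < 27; q++) {
        if (q == 13 || !nb[q] || comp[q] >= 0) continue;
        int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
        if (std::abs(px - qx) <= 1 && std::abs(py - qy) <= 1 &&
            std::abs(pz - qz) <= 1) {
          comp[q] = ncomp;
          stack[top++] = q;
        }
      }
    }
    ncomp++;
  }
  return ncomp;
}

static int bg_components6(const bool* nb) {
  // 6-components of background within the 18-neighborhood that contain a
  // face neighbor of the center
  bool in18[27];
  for (int i = 0; i < 27; i++) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (m == 1 || m == 2);
  }
  int comp[27];
  for (int i = 0; i < 27; i++) comp[i] = -1;
  int ncomp = 0, counted = 0;
  int stack[27];
  for (int s = 0; s < 27; s++) {
    if (!in18[s] || nb[s] || comp[s] >= 0) continue;
    bool touches_face = false;
    int top = 0;
    stack[top++] = s;
    comp[s] = ncomp;
    while (top > 0) {
      int p = stack[--top];
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      if (std::abs(px - 1) + std::abs(py - 1) + std::abs(pz - 1) == 1)
        touches_face = true;
      for (int q = 0; q < 27; q++) {
        if (!in18[q] || nb[q] || comp[q] >= 0) continue;
        int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
        if (std::abs(px - qx) + std::abs(py - qy) + std::abs(pz - qz) == 1) {
          comp[q] = ncomp;
          stack[top++] = q;
        }
      }
    }
    ncomp++;
    if (touches_face) counted++;
  }
  return counted;
}

class Grid {
public:
  std::vector<char> m;
  int nx, ny, nz;
  Grid(int nx_, int ny_, int nz_) : m((size_t)nx_ * ny_ * nz_), nx(nx_), ny(ny_), nz(nz_) {}
  inline bool at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
    return m[(size_t)z * nx * ny + (size_t)y * nx + x] != 0;
  }
  inline void neighborhood(int x, int y, int z, bool* nb) const {
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++)
          nb[nidx(dx, dy, dz)] = at(x + dx, y + dy, z + dz);
  }
};

static inline int fg_neighbors(const bool* nb) {
  int c = 0;
  for (int i = 0; i < 27; i++)
    if (i != 13 && nb[i]) c++;
  return c;
}

static inline bool is_simple(const bool* nb) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid g(nx, ny, nz);
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t i = 0; i < n; i++) g.m[i] = mask[i] ? 1 : 0;

  // six face directions: candidate border voxels have background on that face
  const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1}, {0, -1, 0},
                          {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  bool nb[27];
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++)
          for (int x = 0; x < nx; x++) {
            R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
            if (!g.m[i]) continue;
            if (g.at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            g.neighborhood(x, y, z, nb);
            int nn = fg_neighbors(nb);
            if (nn <= 1) continue; // endpoint or isolated voxel: keep
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential deletion with re-check preserves topology
      for (R_xlen_t i : cand) {
        int z = (int)(i / ((R_xlen_t)nx * ny));
        int rem = (int)(i % ((R_xlen_t)nx * ny));
        int y = rem / nx, x = rem % nx;
        g.neighborhood(x, y, z, nb);
        int nn = fg_neighbors(nb);
        if (nn <= 1) continue;
        if (is_simple(nb)) {
          g.m[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = g.m[i] != 0;
  return out;
}
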