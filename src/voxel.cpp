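#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected component of a 3D logical array containing a seed voxel.
// connectivity: 6 or 26. Seed is a 0-based linear index. Returns a logical
// array (same dim) marking the component.
// [[Rcpp::export(name = ".cc_from_seed")]]
LogicalVector cc_from_seed(LogicalVector mask, IntegerVector dim, int seed,
                           int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (seed < 0 || seed >= n) stop("seed index out of bounds");
  if (!mask[seed]) stop("seed voxel is not in the thresholded set");

  std::vector<char> vis(n, 0);
  std::vector<int> stack;
  stack.reserve(1024);
  stack.push_back(seed);
  vis[seed] = 1;

  // neighbor offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nn = (int)dxs.size();

  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int x = cur % nx;
    int y = (cur / nx) % ny;
    int z = cur / (nx * ny);
    for (int k = 0; k < nn; ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int idx = xx + nx * (yy + ny * zz);
      if (!vis[idx] && mask[idx]) {
        vis[idx] = 1;
        stack.push_back(idx);
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (vis[i] != 0);
  out.attr("dim") = dim;
  return out;
}
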