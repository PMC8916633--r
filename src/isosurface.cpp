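#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isosurface of a binary 3D field at level 0.5, extracted per cube cell via
// the Kuhn 6-tetrahedra decomposition. The decomposition splits every cube
// face by the same diagonal in adjacent cells, so the extracted surface is
// watertight by construction. Surface vertices sit at midpoints of lattice
// edges whose endpoints straddle the level; triangle winding is chosen so the
// outward normal points from inside (field 1) toward outside (field 0).
//
// field: logical array (voxel-center samples), dim = c(nx, ny, nz)
// spacing, origin: mm; node i (0-based) sits at origin + i * spacing
// Returns list(vertices = N x 3 matrix (mm), faces = M x 3 integer, 1-based)
// [[Rcpp::export(name = ".isosurface_tet")]]
List isosurface_tet(LogicalVector field, IntegerVector dim,
                    NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (field.size() != n) stop("field length does not match dim");

  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> verts;  // x,y,z triplets
  std::vector<int> faces;     // 0-based triplets

  auto node_lin = [&](int x, int y, int z) -> uint64_t {
    return (uint64_t)x + (uint64_t)nx * ((uint64_t)y + (uint64_t)ny * (uint64_t)z);
  };
  auto node_val = [&](int x, int y, int z) -> bool {
    return field[(R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z)];
  };

  // vertex on the edge between two lattice nodes (midpoint: binary field)
  auto edge_vertex = [&](uint64_t a, uint64_t b) -> int {
    if (a > b) std::swap(a, b);
    uint64_t pair_key = a * (uint64_t)n + b;  // exact: a,b < n and n^2 < 2^64
    auto it = edge_vert.find(pair_key);
    if (it != edge_vert.end()) return it->second;
    int ax = (int)(a % nx), ay = (int)((a / nx) % ny), az = (int)(a / ((uint64_t)nx * ny));
    int bx = (int)(b % nx), by = (int)((b / nx) % ny), bz = (int)(b / ((uint64_t)nx * ny));
    double px = origin[0] + 0.5 * (ax + bx) * spacing[0];
    double py = origin[1] + 0.5 * (ay + by) * spacing[1];
    double pz = origin[2] + 0.5 * (az + bz) * spacing[2];
    int id = (int)(verts.size() / 3);
    verts.push_back(px); verts.push_back(py); verts.push_back(pz);
    edge_vert.emplace(pair_key, id);
    return id;
  };

  // Kuhn tetrahedra: paths 0 -> 7 through the cube corner bitmask lattice.
  static const int perms[6][3] = {
    {1, 2, 4}, {1, 4, 2}, {2, 1, 4}, {2, 4, 1}, {4, 1, 2}, {4, 2, 1}};

  auto emit_tri = [&](int v0, int v1, int v2,
                      double ox, double oy, double oz,
                      double ix, double iy, double iz) {
    // orient so normal points from inside centroid (i) toward outside (o)
    const double *V = verts.data();
    double ax = V[3 * v1] - V[3 * v0], ay = V[3 * v1 + 1] - V[3 * v0 + 1],
           az = V[3 * v1 + 2] - V[3 * v0 + 2];
    double bx = V[3 * v2] - V[3 * v0], by = V[3 * v2 + 1] - V[3 * v0 + 1],
           bz = V[3 * v2 + 2] - V[3 * v0 + 2];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
           nzv = ax * by - ay * bx;
    double dx = ox - ix, dy = oy - iy, dz = oz - iz;
    if (nxv * dx + nyv * dy + nzv * dz >= 0) {
      faces.push_back(v0); faces.push_back(v1); faces.push_back(v2);
    } else {
      faces.push_back(v0); faces.push_back(v2); faces.push_back(v1);
    }
  };

  int cx[8], cy[8], cz[8];
  bool cv[8];
  uint64_t cl[8];

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int b = 0; b < 8; ++b) {
          int bx = x + (b & 1), by = y + ((b >> 1) & 1), bz = z + ((b >> 2) & 1);
          cx[b] = bx; cy[b] = by; cz[b] = bz;
          cv[b] = node_val(bx, by, bz);
          cl[b] = node_lin(bx, by, bz);
          if (cv[b]) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int tet[4];
          tet[0] = 0;
          tet[1] = perms[t][0];
          tet[2] = perms[t][0] | perms[t][1];
          tet[3] = 7;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[tet[k]]) ins[ni++] = tet[k]; else outs[no++] = tet[k];
          }
          if (ni == 0 || ni == 4) continue;

          double icx = 0, icy = 0, icz = 0, ocx = 0, ocy = 0, ocz = 0;
          for (int k = 0; k < ni; ++k) {
            icx += origin[0] + cx[ins[k]] * spacing[0];
            icy += origin[1] + cy[ins[k]] * spacing[1];
            icz += origin[2] + cz[ins[k]] * spacing[2];
          }
          for (int k = 0; k < no; ++k) {
            ocx += origin[0] + cx[outs[k]] * spacing[0];
            ocy += origin[1] + cy[outs[k]] * spacing[1];
            ocz += origin[2] + cz[outs[k]] * spacing[2];
          }
          icx /= ni; icy /= ni; icz /= ni;
          ocx /= no; ocy /= no; ocz /= no;

          if (ni == 1) {
            int a = ins[0];
            int v0 = edge_vertex(cl[a], cl[outs[0]]);
            int v1 = edge_vertex(cl[a], cl[outs[1]]);
            int v2 = edge_vertex(cl[a], cl[outs[2]]);
            emit_tri(v0, v1, v2, ocx, ocy, ocz, icx, icy, icz);
          } else if (ni == 3) {
            int a = outs[0];
            int v0 = edge_vertex(cl[a], cl[ins[0]]);
            int v1 = edge_vertex(cl[a], cl[ins[1]]);
            int v2 = edge_vertex(cl[a], cl[ins[2]]);
            emit_tri(v0, v1, v2, ocx, ocy, ocz, icx, icy, icz);
          } else {  // ni == 2: quad
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int q0 = edge_vertex(cl[A], cl[C]);
            int q1 = edge_vertex(cl[A], cl[D]);
            int q2 = edge_vertex(cl[B], cl[D]);
            int q3 = edge_vertex(cl[B], cl[C]);
            emit_tri(q0, q1, q2, ocx, ocy, ocz, icx, icy, icz);
            emit_tri(q0, q2, q3, ocx, ocy, ocz, icx, icy, icz);
          }
        }
      }

  int nv = (int)(verts.size() / 3);
  int nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = verts[3 * i];
    V(i, 1) = verts[3 * i + 1];
    V(i, 2) = verts[3 * i + 2];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = faces[3 * i] + 1;
    F(i, 1) = faces[3 * i + 1] + 1;
    F(i, 2) = faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
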