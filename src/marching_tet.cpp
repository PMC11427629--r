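#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on a regular grid.
// Each grid cell is split into 6 tetrahedra sharing the main diagonal, which
// guarantees a closed, manifold, consistently oriented triangle mesh for any
// scalar field with no iso-crossing on the grid boundary. Triangle winding is
// chosen per-tet so that face normals point from the interior (field > iso)
// towards the exterior (field < iso).

struct VertexBank {
  // dedupe interpolated vertices by the (sorted) pair of grid-node ids
  std::map<std::pair<int, int>, int> seen;
  std::vector<double> xyz;
  int add(int a, int b, double t, const std::vector<double>& gx,
          const std::vector<double>& gy, const std::vector<double>& gz) {
    std::pair<int, int> key = a < b ? std::make_pair(a, b) : std::make_pair(b, a);
    if (a > b) t = 1.0 - t;
    // weld crossings that land on a grid node: key by the node itself, so
    // coincident vertices from different edges share one id and the mesh
    // stays manifold
    if (t < 1e-9) { key = std::make_pair(key.first, key.first); t = 0.0; }
    else if (t > 1.0 - 1e-9) { key = std::make_pair(key.second, key.second); t = 1.0; }
    std::map<std::pair<int, int>, int>::iterator it = seen.find(key);
    if (it != seen.end()) return it->second;
    int id = (int)(xyz.size() / 3);
    int lo = key.first, hi = key.second;
    xyz.push_back(gx[lo] + t * (gx[hi] - gx[lo]));
    xyz.push_back(gy[lo] + t * (gy[hi] - gy[lo]));
    xyz.push_back(gz[lo] + t * (gz[hi] - gz[lo]));
    seen.insert(std::make_pair(key, id));
    return id;
  }
};

static inline double interp_t(double va, double vb, double iso) {
  double d = vb - va;
  if (d == 0.0) return 0.5;
  double t = (iso - va) / d;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  return t;
}

// [[Rcpp::export(name = ".marching_tet")]]
List marching_tet(NumericVector field, IntegerVector dims, NumericVector origin,
                  double spacing, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> gx((size_t)nx * ny * nz), gy(gx.size()), gz(gx.size());
  // grid node linear index: i + nx*(j + ny*k), matching R array order
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        gx[id] = origin[0] + i * spacing;
        gy[id] = origin[1] + j * spacing;
        gz[id] = origin[2] + k * spacing;
      }

  // 6-tet decomposition of the unit cube along diagonal 0-6 (corner bit order
  // c = (dx, dy, dz) -> dx + 2*dy + 4*dz)
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 7, 5}, {0, 5, 7, 4},
    {0, 4, 7, 6}, {0, 6, 7, 2}, {0, 2, 7, 3}};
  static const int corner_off[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                                       {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};

  VertexBank bank;
  std::vector<int> faces;

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int nid[8];
        double val[8];
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner_off[c][0], jj = j + corner_off[c][1], kk = k + corner_off[c][2];
          nid[c] = ii + nx * (jj + ny * kk);
          val[c] = field[nid[c]];
        }
        for (int t = 0; t < 6; ++t) {
          int v[4];
          double f[4];
          int nin = 0;
          bool in[4];
          for (int c = 0; c < 4; ++c) {
            v[c] = nid[tets[t][c]];
            f[c] = val[tets[t][c]];
            in[c] = f[c] > iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // collect the crossing edges and emit 1 or 2 triangles
          int tri[2][3];
          int ntri = 0;
          if (nin == 1 || nin == 3) {
            int apex = -1;
            bool apex_in = (nin == 1);
            for (int c = 0; c < 4; ++c)
              if (in[c] == apex_in) apex = c;
            int others[3], no = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) others[no++] = c;
            for (int c = 0; c < 3; ++c) {
              int o = others[c];
              tri[0][c] = bank.add(v[apex], v[o], interp_t(f[apex], f[o], iso), gx, gy, gz);
            }
            ntri = 1;
          } else {  // 2 in, 2 out -> quad split into two triangles
            int ins[2], outs[2], ni2 = 0, no2 = 0;
            for (int c = 0; c < 4; ++c)
              (in[c] ? ins[ni2++] : outs[no2++]) = c;
            int e00 = bank.add(v[ins[0]], v[outs[0]], interp_t(f[ins[0]], f[outs[0]], iso), gx, gy, gz);
            int e01 = bank.add(v[ins[0]], v[outs[1]], interp_t(f[ins[0]], f[outs[1]], iso), gx, gy, gz);
            int e10 = bank.add(v[ins[1]], v[outs[0]], interp_t(f[ins[1]], f[outs[0]], iso), gx, gy, gz);
            int e11 = bank.add(v[ins[1]], v[outs[1]], interp_t(f[ins[1]], f[outs[1]], iso), gx, gy, gz);
            tri[0][0] = e00; tri[0][1] = e01; tri[0][2] = e11;
            tri[1][0] = e00; tri[1][1] = e11; tri[1][2] = e10;
            ntri = 2;
          }
          // orient: normal must point from inside-corner centroid to outside
          double gcx = 0, gcy = 0, gcz = 0, hcx = 0, hcy = 0, hcz = 0;
          int gn = 0, hn = 0;
          for (int c = 0; c < 4; ++c) {
            if (in[c]) { gcx += gx[v[c]]; gcy += gy[v[c]]; gcz += gz[v[c]]; ++gn; }
            else       { hcx += gx[v[c]]; hcy += gy[v[c]]; hcz += gz[v[c]]; ++hn; }
          }
          gcx /= gn; gcy /= gn; gcz /= gn; hcx /= hn; hcy /= hn; hcz /= hn;
          for (int q = 0; q < ntri; ++q) {
            int a = tri[q][0], b = tri[q][1], c = tri[q][2];
            if (a == b || b == c || a == c) continue;  // degenerate sliver
            double ax = bank.xyz[3 * a], ay = bank.xyz[3 * a + 1], az = bank.xyz[3 * a + 2];
            double ux = bank.xyz[3 * b] - ax, uy = bank.xyz[3 * b + 1] - ay, uz = bank.xyz[3 * b + 2] - az;
            double wx = bank.xyz[3 * c] - ax, wy = bank.xyz[3 * c + 1] - ay, wz = bank.xyz[3 * c + 2] - az;
            double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
            double d = nxv * (hcx - gcx) + nyv * (hcy - gcy) + nzv * (hcz - gcz);
            if (d < 0) { int tmp = b; b = c; c = tmp; }
            faces.push_back(a); faces.push_back(b); faces.push_back(c);
          }
        }
      }

  int nv = (int)(bank.xyz.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int r = 0; r < nv; ++r) {
    V(r, 0) = bank.xyz[3 * r];
    V(r, 1) = bank.xyz[3 * r + 1];
    V(r, 2) = bank.xyz[3 * r + 2];
  }
  IntegerMatrix F(nf, 3);
  for (int r = 0; r < nf; ++r) {
    F(r, 0) = faces[3 * r] + 1;  // 1-based for R
    F(r, 1) = faces[3 * r + 1] + 1;
    F(r, 2) = faces[3 * r + 2] + 1;
  }
  return List::create(_["V"] = V, _["F"] = F);
}
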