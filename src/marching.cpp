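#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Isosurface of a scalar field sampled on a regular grid, by marching
// tetrahedra: each lattice cube is split into six tetrahedra around the main
// diagonal, and the level surface is interpolated linearly on tetrahedron
// edges. Vertices are shared through a global edge hash, so the output is a
// watertight manifold wherever the level set stays inside the grid; cells
// outside the grid are simply absent, so a region touching the grid border
// yields an open surface. Triangles are oriented with normals pointing from
// values above `level` towards values below (outward for a solid mask).
//
// Returns vertices in continuous 0-based voxel-index coordinates; the caller
// maps them to world mm through the volume affine.

static const int TET[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

// cube corner offsets (x, y, z)
static const int COFF[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

struct EdgePoint {
  double x, y, z;
};

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector field, IntegerVector dims,
                             double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = field.begin();
  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  std::unordered_map<uint64_t, int> edge_index;
  std::vector<EdgePoint> verts;
  std::vector<int> tris;  // 0-based vertex indices, 3 per triangle

  auto edge_vertex = [&](int64_t ga, int64_t gb, double va, double vb,
                         const int *ca, const int *cb,
                         int ci, int cj, int ck) -> int {
    if (ga > gb) {
      std::swap(ga, gb);
      std::swap(va, vb);
      std::swap(ca, cb);
    }
    uint64_t key = (uint64_t)ga * (uint64_t)(nx * (int64_t)ny * nz) + (uint64_t)gb;
    auto it = edge_index.find(key);
    if (it != edge_index.end()) return it->second;
    double t = (level - va) / (vb - va);
    EdgePoint p;
    p.x = (ci + ca[0]) + t * (cb[0] - ca[0]);
    p.y = (cj + ca[1]) + t * (cb[1] - ca[1]);
    p.z = (ck + ca[2]) + t * (cb[2] - ca[2]);
    int idx = (int)verts.size();
    verts.push_back(p);
    edge_index.emplace(key, idx);
    return idx;
  };

  // emit triangle (i0,i1,i2), flipped if needed so its normal points away
  // from the inside reference point (rx,ry,rz)
  auto emit = [&](int i0, int i1, int i2, double rx, double ry, double rz) {
    const EdgePoint &a = verts[i0], &b = verts[i1], &c = verts[i2];
    double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
    double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
    double nxn = uy * vz - uz * vy;
    double nyn = uz * vx - ux * vz;
    double nzn = ux * vy - uy * vx;
    double cx = (a.x + b.x + c.x) / 3.0 - rx;
    double cy = (a.y + b.y + c.y) / 3.0 - ry;
    double cz = (a.z + b.z + c.z) / 3.0 - rz;
    if (nxn * cx + nyn * cy + nzn * cz >= 0) {
      tris.push_back(i0); tris.push_back(i1); tris.push_back(i2);
    } else {
      tris.push_back(i0); tris.push_back(i2); tris.push_back(i1);
    }
  };

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        double cv[8];
        int64_t cg[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cg[c] = gid(i + COFF[c][0], j + COFF[c][1], k + COFF[c][2]);
          cv[c] = f[cg[c]];
          if (cv[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int a = TET[t][0], b = TET[t][1], c = TET[t][2], d = TET[t][3];
          int ins[4], outs[4];
          int nin = 0, nout = 0;
          int vid[4] = {a, b, c, d};
          for (int q = 0; q < 4; ++q) {
            if (cv[vid[q]] > level) ins[nin++] = vid[q];
            else outs[nout++] = vid[q];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? ins[0] : outs[0];
            int others[3];
            int m = 0;
            for (int q = 0; q < 4; ++q)
              if (vid[q] != apex) others[m++] = vid[q];
            int e0 = edge_vertex(cg[apex], cg[others[0]], cv[apex], cv[others[0]],
                                 COFF[apex], COFF[others[0]], i, j, k);
            int e1 = edge_vertex(cg[apex], cg[others[1]], cv[apex], cv[others[1]],
                                 COFF[apex], COFF[others[1]], i, j, k);
            int e2 = edge_vertex(cg[apex], cg[others[2]], cv[apex], cv[others[2]],
                                 COFF[apex], COFF[others[2]], i, j, k);
            // reference point on the inside of the surface
            int ref = (nin == 1) ? ins[0] : ins[0];
            double rx = i + COFF[ref][0], ry = j + COFF[ref][1], rz = k + COFF[ref][2];
            emit(e0, e1, e2, rx, ry, rz);
          } else {  // nin == 2: quad cut
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int eac = edge_vertex(cg[A], cg[C], cv[A], cv[C], COFF[A], COFF[C], i, j, k);
            int ead = edge_vertex(cg[A], cg[D], cv[A], cv[D], COFF[A], COFF[D], i, j, k);
            int ebd = edge_vertex(cg[B], cg[D], cv[B], cv[D], COFF[B], COFF[D], i, j, k);
            int ebc = edge_vertex(cg[B], cg[C], cv[B], cv[C], COFF[B], COFF[C], i, j, k);
            double rx = (i + COFF[A][0] + i + COFF[B][0]) / 2.0;
            double ry = (j + COFF[A][1] + j + COFF[B][1]) / 2.0;
            double rz = (k + COFF[A][2] + k + COFF[B][2]) / 2.0;
            emit(eac, ead, ebd, rx, ry, rz);
            emit(eac, ebd, ebc, rx, ry, rz);
          }
        }
      }
    }
  }

  NumericMatrix V(verts.size(), 3);
  for (size_t v = 0; v < verts.size(); ++v) {
    V(v, 0) = verts[v].x;
    V(v, 1) = verts[v].y;
    V(v, 2) = verts[v].z;
  }
  IntegerMatrix F(tris.size() / 3, 3);
  for (size_t t = 0; t < tris.size() / 3; ++t) {
    F(t, 0) = tris[3 * t] + 1;
    F(t, 1) = tris[3 * t + 1] + 1;
    F(t, 2) = tris[3 * t + 2] + 1;
  }
  return List::create(Named("vertices") = V, Named("faces") = F);
}
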