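// Isosurface extraction on a binary voxel mask: each grid cube is split
// into six tetrahedra and the iso-0.5 surface is triangulated per
// tetrahedron (vertices at linear interpolation points on tetra edges,
// i.e. edge midpoints for 0/1 data). The mask is zero-padded so the
// surface is closed at the array borders. Vertices are exactly
// deduplicated (all coordinates are multiples of 1/2), so meshes are
// suitable for Euler-characteristic and watertightness checks.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// vertex coordinates are quantized (x2^21) for exact dedup: interpolated
// vertices on a shared cell edge are computed from the same endpoint pair
// in every incident cell, so their float coordinates agree bitwise
struct Key {
  long long x, y, z;
  bool operator==(const Key& o) const { return x == o.x && y == o.y && z == o.z; }
};
struct KeyHash {
  size_t operator()(const Key& k) const {
    size_t h = std::hash<long long>()(k.x);
    h ^= std::hash<long long>()(k.y) + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    h ^= std::hash<long long>()(k.z) + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    return h;
  }
};

struct MeshBuilder {
  std::unordered_map<Key, int, KeyHash> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri; // 0-based triples

  int vertex(double x, double y, double z) {
    const double q = 2097152.0; // 2^21
    Key k{(long long)std::llround(x * q), (long long)std::llround(y * q),
          (long long)std::llround(z * q)};
    auto it = vmap.find(k);
    if (it != vmap.end()) return it->second;
    int id = (int)vx.size();
    vmap.emplace(k, id);
    vx.push_back(x);
    vy.push_back(y);
    vz.push_back(z);
    return id;
  }
  void add_tri(int a, int b, int c) {
    if (a == b || b == c || a == c) return; // degenerate
    tri.push_back(a);
    tri.push_back(b);
    tri.push_back(c);
  }
};

struct P3 { double x, y, z; };

inline P3 interp(const P3& a, const P3& b, double fa, double fb, double iso) {
  double t = (iso - fa) / (fb - fa);
  return P3{a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

// triangulate iso-surface inside one tetrahedron
void march_tet(MeshBuilder& mb, const P3 p[4], const double f[4], double iso) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = f[i] > iso; if (in[i]) ++nin; }
  if (nin == 0 || nin == 4) return;
  int ins[4], outs[4];
  int ni = 0, no = 0;
  for (int i = 0; i < 4; ++i) (in[i] ? ins[ni++] = i : outs[no++] = i);
  if (nin == 1 || nin == 3) {
    int apex = (nin == 1) ? ins[0] : outs[0];
    int others[3];
    int c = 0;
    for (int i = 0; i < 4; ++i) if (i != apex) others[c++] = i;
    P3 q[3];
    for (int i = 0; i < 3; ++i)
      q[i] = interp(p[apex], p[others[i]], f[apex], f[others[i]], iso);
    int a = mb.vertex(q[0].x, q[0].y, q[0].z);
    int b = mb.vertex(q[1].x, q[1].y, q[1].z);
    int d = mb.vertex(q[2].x, q[2].y, q[2].z);
    mb.add_tri(a, b, d);
  } else { // 2 in, 2 out -> quad
    int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
    P3 q0 = interp(p[A], p[C], f[A], f[C], iso);
    P3 q1 = interp(p[A], p[D], f[A], f[D], iso);
    P3 q2 = interp(p[B], p[D], f[B], f[D], iso);
    P3 q3 = interp(p[B], p[C], f[B], f[C], iso);
    int a = mb.vertex(q0.x, q0.y, q0.z);
    int b = mb.vertex(q1.x, q1.y, q1.z);
    int c = mb.vertex(q2.x, q2.y, q2.z);
    int d = mb.vertex(q3.x, q3.y, q3.z);
    mb.add_tri(a, b, c);
    mb.add_tri(a, c, d);
  }
}

} // namespace

// field: numeric array; returns vertices (voxel coordinates, 0-based
// array indices) of the `iso` level set and 1-based triangle indices.
// The grid is zero-padded so surfaces close at the array borders.
// [[Rcpp::export]]
List cpp_isosurface(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // padded grid: index -1 .. n (value 0 outside)
  auto val = [&](int x, int y, int z) -> double {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0.0;
    return field[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
  };
  // six tetrahedra around the main diagonal c0-c6 of each cube
  static const int tets[6][4] = {
      {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
      {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  static const int cdx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  static const int cdy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int cdz[8] = {0, 0, 0, 0, 1, 1, 1, 1};

  MeshBuilder mb;
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double cf[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          cf[c] = val(x + cdx[c], y + cdy[c], z + cdz[c]);
          if (cf[c] > iso) any = true; else all = false;
        }
        if (!any || all) continue;
        P3 cp[8];
        for (int c = 0; c < 8; ++c)
          cp[c] = P3{(double)(x + cdx[c]), (double)(y + cdy[c]),
                     (double)(z + cdz[c])};
        for (int t = 0; t < 6; ++t) {
          P3 tp[4];
          double tf[4];
          for (int v = 0; v < 4; ++v) { tp[v] = cp[tets[t][v]]; tf[v] = cf[tets[t][v]]; }
          march_tet(mb, tp, tf, iso);
        }
      }

  int nv = (int)mb.vx.size();
  int nt = (int)(mb.tri.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = mb.vx[i]; V(i, 1) = mb.vy[i]; V(i, 2) = mb.vz[i]; }
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i) {
    F(i, 0) = mb.tri[3 * i] + 1;
    F(i, 1) = mb.tri[3 * i + 1] + 1;
    F(i, 2) = mb.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
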