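// Exact Euclidean distance / feature transforms and separable Gaussian
// blur for 3D voxel arrays. Used by the phantom generator (surface-inward
// degradation layers, PSF emulation) and by the strut-region partition
// (escape direction = vector to nearest background voxel).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D lower-envelope-of-parabolas distance transform (squared distances),
// with the argmin source position recorded for feature recovery.
static void dt1d(const std::vector<double>& f, int n,
                 std::vector<double>& d, std::vector<int>& arg) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
    arg[q] = v[k];
  }
}

// Squared EDT with nearest-background feature transform.
// mask: integer array, non-zero = foreground (object). Distances are from
// every voxel to the nearest zero (background) voxel; background voxels get
// distance 0 and themselves as feature. Returns dist (voxels) and the
// 1-based linear index of the nearest background voxel.
// [[Rcpp::export]]
List cpp_edt_feature(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> D(n);
  std::vector<int> feat(n); // linear index of nearest bg so far
  // init
  for (size_t i = 0; i < n; ++i) {
    if (mask[i] == 0) { D[i] = 0.0; feat[i] = (int)i; }
    else { D[i] = DT_INF; feat[i] = -1; }
  }
  auto idx = [nx, ny](int x, int y, int z) -> size_t {
    return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
  };
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    std::vector<int> a(nx);
    std::vector<int> fx(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) { f[x] = D[idx(x, y, z)]; fx[x] = feat[idx(x, y, z)]; }
        dt1d(f, nx, d, a);
        for (int x = 0; x < nx; ++x) {
          size_t i = idx(x, y, z);
          D[i] = d[x];
          feat[i] = fx[a[x]];
        }
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    std::vector<int> a(ny);
    std::vector<int> fy(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) { f[y] = D[idx(x, y, z)]; fy[y] = feat[idx(x, y, z)]; }
        dt1d(f, ny, d, a);
        for (int y = 0; y < ny; ++y) {
          size_t i = idx(x, y, z);
          D[i] = d[y];
          feat[i] = fy[a[y]];
        }
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    std::vector<int> a(nz);
    std::vector<int> fz(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) { f[z] = D[idx(x, y, z)]; fz[z] = feat[idx(x, y, z)]; }
        dt1d(f, nz, d, a);
        for (int z = 0; z < nz; ++z) {
          size_t i = idx(x, y, z);
          D[i] = d[z];
          feat[i] = fz[a[z]];
        }
      }
  }
  NumericVector dist(n);
  IntegerVector feature(n);
  for (size_t i = 0; i < n; ++i) {
    dist[i] = D[i] >= DT_INF ? R_PosInf : std::sqrt(D[i]);
    feature[i] = feat[i] < 0 ? NA_INTEGER : feat[i] + 1; // 1-based
  }
  return List::create(_["dist"] = dist, _["feature"] = feature);
}

// Separable Gaussian blur, sigma in voxels, replicate boundary.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3(NumericVector vol, IntegerVector dims,
                                 double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (auto& k : ker) k /= s;

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  auto idx = [nx, ny](int x, int y, int z) -> size_t {
    return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
  };
  auto clampi = [](int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); };
  // x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int t = -r; t <= r; ++t)
          acc += ker[t + r] * a[idx(clampi(x + t, 0, nx - 1), y, z)];
        b[idx(x, y, z)] = acc;
      }
  std::swap(a, b);
  // y
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int t = -r; t <= r; ++t)
          acc += ker[t + r] * a[idx(x, clampi(y + t, 0, ny - 1), z)];
        b[idx(x, y, z)] = acc;
      }
  std::swap(a, b);
  // z
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int t = -r; t <= r; ++t)
          acc += ker[t + r] * a[idx(x, y, clampi(z + t, 0, nz - 1))];
        b[idx(x, y, z)] = acc;
      }
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}
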