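// Exact Euclidean distance transform, 3D, anisotropic spacing.
// Felzenszwalb & Huttenlocher lower-envelope-of-parabolas scheme applied
// separably along each axis on squared distances.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// large finite stand-in for "no background on this line yet"
static const double DT_BIG = 1e30;
static const double DT_INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform with sample spacing h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt3")]]
NumericVector cpp_edt3(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? DT_BIG : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x (fastest-varying)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = d[z];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= DT_BIG) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
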