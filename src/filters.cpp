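// Separable Gaussian smoothing and multiscale Hessian (Frangi) vesselness.
// Works in voxel units; callers convert physical scales to voxels.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // reflect-101 boundary
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static void blur_axis(std::vector<double>& g, int nx, int ny, int nz,
                      int axis, const std::vector<double>& kern) {
  const int r = (int)kern.size() / 2;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  const int a1 = (axis == 0) ? 1 : 0;
  const int a2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[a2]; ++j2)
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      R_xlen_t base = (R_xlen_t)j1 * stride[a1] + (R_xlen_t)j2 * stride[a2];
      for (int i = 0; i < len; ++i) line[i] = g[base + (R_xlen_t)i * st];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int k = -r; k <= r; ++k)
          acc += kern[k + r] * line[reflect(i + k, len)];
        g[base + (R_xlen_t)i * st] = acc;
      }
    }
}

// [[Rcpp::export(name = ".cpp_gaussian_blur3")]]
NumericVector cpp_gaussian_blur3(NumericVector vol, IntegerVector dim,
                                 double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(vol.begin(), vol.end());
  if (sigma > 0) {
    int r = std::max(1, (int)std::ceil(3.5 * sigma));
    std::vector<double> kern(2 * r + 1);
    double s = 0;
    for (int k = -r; k <= r; ++k) {
      kern[k + r] = std::exp(-0.5 * k * k / (sigma * sigma));
      s += kern[k + r];
    }
    for (double& v : kern) v /= s;
    for (int ax = 0; ax < 3; ++ax) blur_axis(g, nx, ny, nz, ax, kern);
  }
  NumericVector out(n);
  std::copy(g.begin(), g.end(), out.begin());
  return out;
}

// Jacobi eigendecomposition for a symmetric 3x3 matrix. Deterministic.
static void eig3(double a[3][3], double lam[3], double vec[3][3]) {
  double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-14) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1));
        double c = 1 / std::sqrt(t * t + 1), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
  }
  for (int i = 0; i < 3; ++i) {
    lam[i] = a[i][i];
    for (int k = 0; k < 3; ++k) vec[k][i] = v[k][i];
  }
}

// Frangi vesselness for bright tubes at given voxels of a pre-smoothed volume.
// idx: 0-based linear indices. sigma: scale (voxels) for gamma-normalization.
// c <= 0 requests the conventional auto setting (half the max Frobenius norm).
// [[Rcpp::export(name = ".cpp_vesselness")]]
List cpp_vesselness(NumericVector vol, IntegerVector dim, IntegerVector idx,
                    double sigma, double alpha, double beta, double c) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t m = idx.size();
  NumericVector ves(m);
  NumericMatrix orient(m, 3);
  std::vector<double> l1(m), l2(m), l3(m), S(m);
  std::vector<double> evec(3 * m);
  const double g2 = sigma * sigma; // gamma-normalization (gamma = 2)

  for (R_xlen_t t = 0; t < m; ++t) {
    R_xlen_t i = idx[t];
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / sz);
    if (x < 1 || y < 1 || z < 1 || x >= nx - 1 || y >= ny - 1 || z >= nz - 1) {
      l1[t] = l2[t] = l3[t] = 0;
      evec[3 * t] = 1;
      continue;
    }
    double h[3][3];
    double c0 = vol[i];
    h[0][0] = vol[i - sx] - 2 * c0 + vol[i + sx];
    h[1][1] = vol[i - sy] - 2 * c0 + vol[i + sy];
    h[2][2] = vol[i - sz] - 2 * c0 + vol[i + sz];
    h[0][1] = h[1][0] =
        (vol[i + sx + sy] - vol[i + sx - sy] - vol[i - sx + sy] + vol[i - sx - sy]) / 4;
    h[0][2] = h[2][0] =
        (vol[i + sx + sz] - vol[i + sx - sz] - vol[i - sx + sz] + vol[i - sx - sz]) / 4;
    h[1][2] = h[2][1] =
        (vol[i + sy + sz] - vol[i + sy - sz] - vol[i - sy + sz] + vol[i - sy - sz]) / 4;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) h[a][b] *= g2;

    double lam[3], vec[3][3];
    eig3(h, lam, vec);
    // sort by |lambda| ascending
    int ord[3] = {0, 1, 2};
    for (int a = 0; a < 2; ++a)
      for (int b = a + 1; b < 3; ++b)
        if (std::fabs(lam[ord[b]]) < std::fabs(lam[ord[a]]))
          std::swap(ord[a], ord[b]);
    l1[t] = lam[ord[0]];
    l2[t] = lam[ord[1]];
    l3[t] = lam[ord[2]];
    S[t] = std::sqrt(lam[0] * lam[0] + lam[1] * lam[1] + lam[2] * lam[2]);
    for (int k = 0; k < 3; ++k) evec[3 * t + k] = vec[k][ord[0]];
  }

  double cc = c;
  if (cc <= 0) {
    double smax = 0;
    for (R_xlen_t t = 0; t < m; ++t) smax = std::max(smax, S[t]);
    cc = (smax > 0) ? smax / 2 : 1.0;
  }
  for (R_xlen_t t = 0; t < m; ++t) {
    double v = 0;
    if (l2[t] < 0 && l3[t] < 0) {
      double ra = std::fabs(l2[t]) / std::fabs(l3[t]);
      double rb = std::fabs(l1[t]) / std::sqrt(std::fabs(l2[t] * l3[t]));
      v = (1 - std::exp(-ra * ra / (2 * alpha * alpha))) *
          std::exp(-rb * rb / (2 * beta * beta)) *
          (1 - std::exp(-S[t] * S[t] / (2 * cc * cc)));
    }
    ves[t] = v;
    // unit orientation (eigenvector of smallest |lambda|), sign canonical
    double ox = evec[3 * t], oy = evec[3 * t + 1], oz = evec[3 * t + 2];
    double nrm = std::sqrt(ox * ox + oy * oy + oz * oz);
    if (nrm < 1e-12) { ox = 1; oy = 0; oz = 0; nrm = 1; }
    ox /= nrm; oy /= nrm; oz /= nrm;
    if (oz < 0 || (oz == 0 && (oy < 0 || (oy == 0 && ox < 0)))) {
      ox = -ox; oy = -oy; oz = -oz;
    }
    orient(t, 0) = ox; orient(t, 1) = oy; orient(t, 2) = oz;
  }
  return List::create(_["vesselness"] = ves, _["orientation"] = orient);
}
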