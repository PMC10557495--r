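// Multi-stencils fast marching: solves |grad T| * F = 1 with T(root) = 0.
// Second-order upwind differences on the axis frame where available;
// updates are taken as the minimum over several orthogonal stencils
// (axis-aligned plus face-diagonal frames), which reduces the directional
// bias of classic single-stencil FMM.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
using namespace Rcpp;

struct Dir { int off[3]; double h; };
struct Stencil { Dir d[3]; };

// [[Rcpp::export(name = ".cpp_msfm")]]
NumericVector cpp_msfm(NumericVector speed, IntegerVector dim,
                       NumericVector spacing, IntegerVector sources,
                       bool second_order = true) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<Stencil> stencils;
  {
    auto hlen = [&](int a, int b, int c) {
      return std::sqrt(a * a * sx * sx + b * b * sy * sy + c * c * sz * sz);
    };
    auto add = [&](int d1[3], int d2[3], int d3[3]) {
      Stencil s;
      s.d[0] = {{d1[0], d1[1], d1[2]}, hlen(d1[0], d1[1], d1[2])};
      s.d[1] = {{d2[0], d2[1], d2[2]}, hlen(d2[0], d2[1], d2[2])};
      s.d[2] = {{d3[0], d3[1], d3[2]}, hlen(d3[0], d3[1], d3[2])};
      stencils.push_back(s);
    };
    int ex[3] = {1, 0, 0}, ey[3] = {0, 1, 0}, ez[3] = {0, 0, 1};
    add(ex, ey, ez); // axis stencil, always valid
    const double eps = 1e-9;
    // face-diagonal frames (orthogonal only for matching spacings)
    if (std::fabs(sx - sy) < eps) {
      int a[3] = {1, 1, 0}, b[3] = {1, -1, 0};
      add(a, b, ez);
    }
    if (std::fabs(sx - sz) < eps) {
      int a[3] = {1, 0, 1}, b[3] = {1, 0, -1};
      add(a, b, ey);
    }
    if (std::fabs(sy - sz) < eps) {
      int a[3] = {0, 1, 1}, b[3] = {0, 1, -1};
      add(a, b, ex);
    }
    // note: frames through the body diagonals would need non-orthogonal
    // metric cross terms to be consistent; the axis + face-diagonal set
    // keeps the update quadratic diagonal and leaves a small residual
    // directional bias along body diagonals (documented limitation)
  }

  std::vector<double> T(n, INF);
  std::vector<unsigned char> state(n, 0); // 0 far, 1 trial, 2 frozen

  auto inb = [&](int x, int y, int z) {
    return x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz;
  };
  auto lin = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };

  // solve the upwind quadratic at voxel i, return candidate time
  auto update = [&](int x, int y, int z, R_xlen_t i) -> double {
    double F = speed[i];
    if (!(F > 0)) return INF;
    double invF2 = 1.0 / (F * F);
    double best = INF;
    for (size_t si = 0; si < stencils.size(); ++si) {
      const Stencil& st = stencils[si];
      const bool so = second_order;
      // collect active directions: coefficients (a*T - b)^2, anchor t1
      double A[3], B[3], T1[3];
      bool act[3];
      for (int k = 0; k < 3; ++k) {
        act[k] = false;
        double t1 = INF, t2 = INF;
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          int x1 = x + sgn * st.d[k].off[0], y1 = y + sgn * st.d[k].off[1],
              z1 = z + sgn * st.d[k].off[2];
          if (!inb(x1, y1, z1)) continue;
          R_xlen_t i1 = lin(x1, y1, z1);
          if (state[i1] != 2) continue;
          if (T[i1] < t1) {
            t1 = T[i1];
            t2 = INF;
            if (so) {
              int x2 = x + 2 * sgn * st.d[k].off[0],
                  y2 = y + 2 * sgn * st.d[k].off[1],
                  z2 = z + 2 * sgn * st.d[k].off[2];
              if (inb(x2, y2, z2)) {
                R_xlen_t i2 = lin(x2, y2, z2);
                if (state[i2] == 2 && T[i2] <= T[i1]) t2 = T[i2];
              }
            }
          }
        }
        if (t1 < INF) {
          act[k] = true;
          T1[k] = t1;
          double h = st.d[k].h;
          if (t2 < INF) { A[k] = 1.5 / h; B[k] = (4 * t1 - t2) / (2 * h); }
          else          { A[k] = 1.0 / h; B[k] = t1 / h; }
        }
      }
      // iteratively solve, dropping the direction with the largest anchor
      // when causality fails
      while (true) {
        double sa = 0, sb = 0, sc = -invF2, tmax = -INF;
        int kmax = -1, nact = 0;
        for (int k = 0; k < 3; ++k)
          if (act[k]) {
            ++nact;
            sa += A[k] * A[k];
            sb += A[k] * B[k];
            sc += B[k] * B[k];
            if (T1[k] > tmax) { tmax = T1[k]; kmax = k; }
          }
        if (nact == 0) break;
        double disc = sb * sb - sa * sc;
        if (disc >= 0) {
          double t = (sb + std::sqrt(disc)) / sa;
          if (t >= tmax - 1e-12) {
            if (t < best) best = t;
            break;
          }
        }
        act[kmax] = false; // violated causality: drop and retry
      }
    }
    return best;
  };

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;
  for (int s = 0; s < sources.size(); ++s) {
    R_xlen_t i = sources[s];
    if (i < 0 || i >= n) stop("source index out of range");
    if (!(speed[i] > 0)) stop("source lies outside the traversable region");
    T[i] = 0;
    state[i] = 1;
    heap.push(QE(0.0, i));
  }

  // update neighborhood: every voxel that can see a newly frozen voxel
  // through some stencil direction (both signs)
  std::vector<std::array<int, 3> > noff;
  {
    std::vector<std::array<int, 3> > all;
    for (const Stencil& st : stencils)
      for (int k = 0; k < 3; ++k)
        for (int sgn = -1; sgn <= 1; sgn += 2)
          all.push_back({sgn * st.d[k].off[0], sgn * st.d[k].off[1],
                         sgn * st.d[k].off[2]});
    for (auto& o : all) {
      bool seen = false;
      for (auto& u : noff)
        if (u[0] == o[0] && u[1] == o[1] && u[2] == o[2]) { seen = true; break; }
      if (!seen) noff.push_back(o);
    }
  }
  const int NB = (int)noff.size();

  while (!heap.empty()) {
    QE top = heap.top();
    heap.pop();
    R_xlen_t i = top.second;
    if (state[i] == 2 || top.first > T[i] + 1e-12) continue;
    state[i] = 2;
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
    for (int k = 0; k < NB; ++k) {
      int x1 = x + noff[k][0], y1 = y + noff[k][1], z1 = z + noff[k][2];
      if (!inb(x1, y1, z1)) continue;
      R_xlen_t i1 = lin(x1, y1, z1);
      if (state[i1] == 2 || !(speed[i1] > 0)) continue;
      double t = update(x1, y1, z1, i1);
      if (t < T[i1]) {
        T[i1] = t;
        state[i1] = 1;
        heap.push(QE(t, i1));
      }
    }
  }

  NumericVector out(n);
  std::copy(T.begin(), T.end(), out.begin());
  return out;
}
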