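// Fixed-radius neighbor search over 3D points (uniform cell hashing) and
// geodesic label propagation inside a mask (multi-source BFS).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline long long cellkey(int cx, int cy, int cz) {
  return ((long long)cx << 42) ^ ((long long)cy << 21) ^ (long long)cz;
}

// Returns all unordered pairs (i, j), 1-based, with ||p_i - p_j|| <= r.
// [[Rcpp::export(name = ".cpp_radius_pairs")]]
DataFrame cpp_radius_pairs(const NumericMatrix& pos, double r) {
  const int n = pos.nrow();
  std::unordered_map<long long, std::vector<int> > grid;
  const double cs = std::max(r, 1e-9);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(pos(i, 0) / cs), cy = (int)std::floor(pos(i, 1) / cs),
        cz = (int)std::floor(pos(i, 2) / cs);
    grid[cellkey(cx, cy, cz)].push_back(i);
  }
  std::vector<int> ii, jj;
  std::vector<double> dd;
  const double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(pos(i, 0) / cs), cy = (int)std::floor(pos(i, 1) / cs),
        cz = (int)std::floor(pos(i, 2) / cs);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          auto it = grid.find(cellkey(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double a = pos(i, 0) - pos(j, 0), b = pos(i, 1) - pos(j, 1),
                   c = pos(i, 2) - pos(j, 2);
            double d2 = a * a + b * b + c * c;
            if (d2 <= r2) {
              ii.push_back(i + 1);
              jj.push_back(j + 1);
              dd.push_back(std::sqrt(d2));
            }
          }
        }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}

// For each row of `query`, index (1-based) of the nearest row of `ref`.
// [[Rcpp::export(name = ".cpp_nearest_ref")]]
IntegerVector cpp_nearest_ref(const NumericMatrix& query,
                              const NumericMatrix& ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < nr; ++j) {
      double a = query(i, 0) - ref(j, 0), b = query(i, 1) - ref(j, 1),
             c = query(i, 2) - ref(j, 2);
      double d2 = a * a + b * b + c * c;
      if (d2 < best) { best = d2; bj = j + 1; }
    }
    out[i] = bj;
  }
  return out;
}

// Propagate nonzero labels to every mask voxel by breadth-first search
// (26-neighborhood) restricted to the mask: geodesic nearest labeled voxel.
// [[Rcpp::export(name = ".cpp_propagate_labels")]]
IntegerVector cpp_propagate_labels(IntegerVector labels, LogicalVector mask,
                                   IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out = clone(labels);
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] != 0 && mask[i]) q.push(i);
  while (!q.empty()) {
    R_xlen_t i = q.front();
    q.pop();
    int x = (int)(i % nx), y = (int)((i / nx) % ny),
        z = (int)(i / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int x1 = x + dx, y1 = y + dy, z1 = z + dz;
          if (x1 < 0 || y1 < 0 || z1 < 0 || x1 >= nx || y1 >= ny || z1 >= nz)
            continue;
          R_xlen_t i1 = (R_xlen_t)z1 * nx * ny + (R_xlen_t)y1 * nx + x1;
          if (mask[i1] && out[i1] == 0) {
            out[i1] = out[i];
            q.push(i1);
          }
        }
  }
  return out;
}
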