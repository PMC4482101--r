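// Voxel-level primitives shared by every stage of the airway pipeline.
// All masks are passed as LogicalVector with an explicit dim of length 3;
// seed indices arriving from R are 1-based.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  Grid(const IntegerVector &dim) : nx(dim[0]), ny(dim[1]), nz(dim[2]) {}
  inline R_xlen_t size() const { return (R_xlen_t)nx * ny * nz; }
  inline R_xlen_t idx(int x, int y, int z) const {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// offsets for 6- and 26-connectivity
const int OFF6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

static std::vector<std::array<int,3>> offsets26() {
  std::vector<std::array<int,3>> v;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) v.push_back({dx, dy, dz});
  return v;
}

} // namespace

// Connected-threshold region growing: voxels with HU strictly below `thr`
// reachable from any seed. connectivity is 6 or 26.
// [[Rcpp::export(name = ".rg_grow_cpp")]]
LogicalVector rg_grow_cpp(NumericVector vol, IntegerVector dim,
                          IntegerMatrix seeds, double thr, int connectivity) {
  Grid g(dim);
  LogicalVector out(g.size(), false);
  std::vector<char> visited(g.size(), 0);
  std::queue<std::array<int,3>> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int x = seeds(s, 0) - 1, y = seeds(s, 1) - 1, z = seeds(s, 2) - 1;
    if (!g.inside(x, y, z)) stop("seed out of bounds");
    R_xlen_t i = g.idx(x, y, z);
    if (vol[i] < thr && !visited[i]) {
      visited[i] = 1;
      out[i] = true;
      q.push({x, y, z});
    }
  }
  std::vector<std::array<int,3>> offs;
  if (connectivity == 6) {
    for (auto &o : OFF6) offs.push_back({o[0], o[1], o[2]});
  } else if (connectivity == 26) {
    offs = offsets26();
  } else stop("connectivity must be 6 or 26");
  while (!q.empty()) {
    auto c = q.front(); q.pop();
    for (auto &o : offs) {
      int x = c[0] + o[0], y = c[1] + o[1], z = c[2] + o[2];
      if (!g.inside(x, y, z)) continue;
      R_xlen_t i = g.idx(x, y, z);
      if (!visited[i] && vol[i] < thr) {
        visited[i] = 1;
        out[i] = true;
        q.push({x, y, z});
      }
    }
  }
  return out;
}

// Label connected components of a mask; background voxels get 0, components
// are numbered 1..n in scan order of their first voxel.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim,
                           int connectivity) {
  Grid g(dim);
  IntegerVector lab(g.size(), 0);
  std::vector<std::array<int,3>> offs;
  if (connectivity == 6) {
    for (auto &o : OFF6) offs.push_back({o[0], o[1], o[2]});
  } else if (connectivity == 26) {
    offs = offsets26();
  } else stop("connectivity must be 6 or 26");
  int next = 0;
  std::queue<std::array<int,3>> q;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t i0 = g.idx(x, y, z);
        if (!mask[i0] || lab[i0]) continue;
        lab[i0] = ++next;
        q.push({x, y, z});
        while (!q.empty()) {
          auto c = q.front(); q.pop();
          for (auto &o : offs) {
            int xx = c[0] + o[0], yy = c[1] + o[1], zz = c[2] + o[2];
            if (!g.inside(xx, yy, zz)) continue;
            R_xlen_t i = g.idx(xx, yy, zz);
            if (mask[i] && !lab[i]) {
              lab[i] = next;
              q.push({xx, yy, zz});
            }
          }
        }
      }
  return lab;
}

// Fill holes: background voxels not 6-connected to the grid border through
// background become foreground.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<char> outside(g.size(), 0);
  std::queue<std::array<int,3>> q;
  auto push_bg = [&](int x, int y, int z) {
    R_xlen_t i = g.idx(x, y, z);
    if (!mask[i] && !outside[i]) { outside[i] = 1; q.push({x, y, z}); }
  };
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x)
        if (x == 0 || y == 0 || z == 0 ||
            x == g.nx - 1 || y == g.ny - 1 || z == g.nz - 1)
          push_bg(x, y, z);
  while (!q.empty()) {
    auto c = q.front(); q.pop();
    for (auto &o : OFF6) {
      int x = c[0] + o[0], y = c[1] + o[1], z = c[2] + o[2];
      if (g.inside(x, y, z)) push_bg(x, y, z);
    }
  }
  LogicalVector out(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Dilation by a Euclidean ball of the given voxel radius (radius 1 is the
// 6-neighbour cross).
// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dim, int radius) {
  Grid g(dim);
  if (radius <= 0) return clone(mask);
  std::vector<std::array<int,3>> offs;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius &&
            (dx || dy || dz))
          offs.push_back({dx, dy, dz});
  LogicalVector out = clone(mask);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        if (!mask[g.idx(x, y, z)]) continue;
        for (auto &o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (g.inside(xx, yy, zz)) out[g.idx(xx, yy, zz)] = true;
        }
      }
  return out;
}

namespace {

// --- simple-point machinery for 3D thinning ------------------------------
// Neighborhood cells are indexed n = (dz+1)*9 + (dy+1)*3 + (dx+1), center 13.

inline void cell_delta(int n, int &dx, int &dy, int &dz) {
  dx = n % 3 - 1; dy = (n / 3) % 3 - 1; dz = n / 9 - 1;
}

// T26: number of 26-components of object voxels in the punctured 3x3x3
// neighborhood. T6: number of 6-components of background voxels in the
// 18-neighborhood that touch a face neighbor of the center.
bool is_simple(const bool nb[27]) {
  // T26 over object cells (center excluded)
  int comp = 0;
  bool seen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comp;
    if (comp > 1) return false;
    std::queue<int> q; q.push(s); seen[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx, cy, cz; cell_delta(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || !nb[t] || seen[t]) continue;
        int tx, ty, tz; cell_delta(t, tx, ty, tz);
        if (std::abs(tx - cx) <= 1 && std::abs(ty - cy) <= 1 &&
            std::abs(tz - cz) <= 1) { seen[t] = true; q.push(t); }
      }
    }
  }
  if (comp != 1) return false;
  // T6 over background cells of the 18-neighborhood
  int comp6 = 0;
  bool seen6[27] = {false};
  auto in18 = [](int n) {
    int dx, dy, dz; cell_delta(n, dx, dy, dz);
    int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
    return l1 >= 1 && l1 <= 2;
  };
  auto is_face = [](int n) {
    int dx, dy, dz; cell_delta(n, dx, dy, dz);
    return std::abs(dx) + std::abs(dy) + std::abs(dz) == 1;
  };
  for (int s = 0; s < 27; ++s) {
    if (!in18(s) || nb[s] || seen6[s] || !is_face(s)) continue;
    // grow the 6-component containing this background face cell
    ++comp6;
    if (comp6 > 1) return false;
    std::queue<int> q; q.push(s); seen6[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx, cy, cz; cell_delta(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (!in18(t) || nb[t] || seen6[t]) continue;
        int tx, ty, tz; cell_delta(t, tx, ty, tz);
        if (std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz) == 1) {
          seen6[t] = true; q.push(t);
        }
      }
    }
  }
  // any background face cell not yet seen would start a second component
  for (int s = 0; s < 27; ++s) {
    int dx, dy, dz; cell_delta(s, dx, dy, dz);
    if (std::abs(dx) + std::abs(dy) + std::abs(dz) == 1 && !nb[s] && !seen6[s])
      return false;
  }
  return comp6 == 1;
}

} // namespace

// Curve thinning: sequentially delete simple, non-endpoint border voxels in
// six directional subiterations until stable; leaves a 1-voxel centerline.
// [[Rcpp::export(name = ".skeletonize_cpp")]]
LogicalVector skeletonize_cpp(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<char> m(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) m[i] = mask[i] ? 1 : 0;
  auto at = [&](int x, int y, int z) -> char {
    return g.inside(x, y, z) ? m[g.idx(x, y, z)] : 0;
  };
  auto n26count = [&](int x, int y, int z) {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if ((dx || dy || dz) && at(x + dx, y + dy, z + dz)) ++c;
    return c;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      const int *o = OFF6[d];
      // candidates: border voxels whose face neighbor in direction d is bg
      std::vector<std::array<int,3>> cand;
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y)
          for (int x = 0; x < g.nx; ++x)
            if (m[g.idx(x, y, z)] && !at(x + o[0], y + o[1], z + o[2]))
              cand.push_back({x, y, z});
      for (auto &c : cand) {
        int x = c[0], y = c[1], z = c[2];
        if (!m[g.idx(x, y, z)]) continue;           // deleted earlier this pass
        if (at(x + o[0], y + o[1], z + o[2])) continue;
        if (n26count(x, y, z) <= 1) continue;       // endpoint: keep
        bool nb[27];
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx)
              nb[k++] = at(x + dx, y + dy, z + dz) != 0;
        if (is_simple(nb)) {
          m[g.idx(x, y, z)] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) out[i] = m[i] != 0;
  return out;
}

// Separable Gaussian smoothing with per-axis sigma in voxels (0 = skip axis);
// truncated at 3 sigma with renormalized edge kernels.
// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  Grid g(dim);
  std::vector<double> cur(vol.begin(), vol.end()), nxt(g.size());
  int n[3] = {g.nx, g.ny, g.nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)g.nx, (R_xlen_t)g.nx * g.ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (s * s));
    // iterate over all lines along axis ax
    int a1 = (ax + 1) % 3, a2 = (ax + 2) % 3;
    for (int i2 = 0; i2 < n[a2]; ++i2)
      for (int i1 = 0; i1 < n[a1]; ++i1) {
        R_xlen_t base = stride[a1] * i1 + stride[a2] * i2;
        for (int i0 = 0; i0 < n[ax]; ++i0) {
          double acc = 0, wsum = 0;
          int lo = std::max(0, i0 - r), hi = std::min(n[ax] - 1, i0 + r);
          for (int j = lo; j <= hi; ++j) {
            double w = k[j - i0 + r];
            acc += w * cur[base + stride[ax] * j];
            wsum += w;
          }
          nxt[base + stride[ax] * i0] = acc / wsum;
        }
      }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}
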