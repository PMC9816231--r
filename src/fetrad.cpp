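#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel grids arrive as flattened column-major arrays (R convention).
// Gray levels use NA_INTEGER for voxels outside the region of interest.

static inline int idx3(int i, int j, int k, const int* d) {
  return i + d[0] * (j + d[1] * k);
}

static inline bool inb(int i, int j, int k, const int* d) {
  return i >= 0 && i < d[0] && j >= 0 && j < d[1] && k >= 0 && k < d[2];
}

// 26-neighbourhood offsets, generated once
static void neigh26(int off[26][3]) {
  int n = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        off[n][0] = a; off[n][1] = b; off[n][2] = c; ++n;
      }
}

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lv, IntegerVector dims, int ng,
                       IntegerMatrix offs) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int na = offs.nrow();
  NumericVector out(ng * ng * na);
  for (int a = 0; a < na; ++a) {
    const int dx = offs(a, 0), dy = offs(a, 1), dz = offs(a, 2);
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          const int v1 = lv[idx3(i, j, k, d)];
          if (v1 == NA_INTEGER) continue;
          const int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (!inb(i2, j2, k2, d)) continue;
          const int v2 = lv[idx3(i2, j2, k2, d)];
          if (v2 == NA_INTEGER) continue;
          out[(v1 - 1) + ng * (v2 - 1) + ng * ng * a] += 1.0;
        }
  }
  return out;
}

// Run-length matrices, one per direction; runs broken by out-of-mask voxels.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lv, IntegerVector dims, int ng,
                        IntegerMatrix dirs) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int nd = dirs.nrow();
  const int lmax = std::max(d[0], std::max(d[1], d[2]));
  NumericVector out(ng * lmax * nd);
  for (int a = 0; a < nd; ++a) {
    const int dx = dirs(a, 0), dy = dirs(a, 1), dz = dirs(a, 2);
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          const int v = lv[idx3(i, j, k, d)];
          if (v == NA_INTEGER) continue;
          // run starts here iff predecessor is absent or different
          const int ip = i - dx, jp = j - dy, kp = k - dz;
          if (inb(ip, jp, kp, d)) {
            const int vp = lv[idx3(ip, jp, kp, d)];
            if (vp == v) continue;
          }
          int len = 1, i2 = i + dx, j2 = j + dy, k2 = k + dz;
          while (inb(i2, j2, k2, d) && lv[idx3(i2, j2, k2, d)] == v) {
            ++len; i2 += dx; j2 += dy; k2 += dz;
          }
          out[(v - 1) + ng * (len - 1) + ng * lmax * a] += 1.0;
        }
  }
  return out;
}

// Size-zone decomposition: 26-connected zones of equal gray level.
// Returns two columns: zone gray level, zone size.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector lv, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  int off[26][3]; neigh26(off);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        const int id0 = idx3(i, j, k, d);
        if (seen[id0] || lv[id0] == NA_INTEGER) continue;
        const int v = lv[id0];
        int size = 0;
        std::queue<std::array<int, 3>> q;
        q.push({i, j, k}); seen[id0] = 1;
        while (!q.empty()) {
          auto p = q.front(); q.pop(); ++size;
          for (int m = 0; m < 26; ++m) {
            const int i2 = p[0] + off[m][0], j2 = p[1] + off[m][1],
                      k2 = p[2] + off[m][2];
            if (!inb(i2, j2, k2, d)) continue;
            const int id2 = idx3(i2, j2, k2, d);
            if (seen[id2] || lv[id2] != v) continue;
            seen[id2] = 1; q.push({i2, j2, k2});
          }
        }
        zl.push_back(v); zs.push_back(size);
      }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) { out(r, 0) = zl[r]; out(r, 1) = zs[r]; }
  return out;
}

// Dependence matrix: counts of 26-neighbours within alpha of the centre level.
// Rows: gray level; columns: dependence count 0..26.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lv, IntegerVector dims, int ng,
                       double alpha) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  NumericMatrix out(ng, 27);
  int off[26][3]; neigh26(off);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        const int v = lv[idx3(i, j, k, d)];
        if (v == NA_INTEGER) continue;
        int dep = 0;
        for (int m = 0; m < 26; ++m) {
          const int i2 = i + off[m][0], j2 = j + off[m][1], k2 = k + off[m][2];
          if (!inb(i2, j2, k2, d)) continue;
          const int v2 = lv[idx3(i2, j2, k2, d)];
          if (v2 == NA_INTEGER) continue;
          if (std::abs(v - v2) <= alpha) ++dep;
        }
        out(v - 1, dep) += 1.0;
      }
  return out;
}

// Neighbourhood gray-tone difference: per level, voxel count and summed
// absolute difference from the mean of in-mask 26-neighbours. Voxels with no
// valid neighbour are excluded.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lv, IntegerVector dims, int ng) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  NumericMatrix out(ng, 2);
  int off[26][3]; neigh26(off);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        const int v = lv[idx3(i, j, k, d)];
        if (v == NA_INTEGER) continue;
        double s = 0.0; int cnt = 0;
        for (int m = 0; m < 26; ++m) {
          const int i2 = i + off[m][0], j2 = j + off[m][1], k2 = k + off[m][2];
          if (!inb(i2, j2, k2, d)) continue;
          const int v2 = lv[idx3(i2, j2, k2, d)];
          if (v2 == NA_INTEGER) continue;
          s += v2; ++cnt;
        }
        if (cnt == 0) continue;
        out(v - 1, 0) += 1.0;
        out(v - 1, 1) += std::fabs(v - s / cnt);
      }
  return out;
}

// Connected-component labelling of a binary volume (26- or 6-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  IntegerVector lab(n);
  int off[26][3]; neigh26(off);
  const int nn = (connectivity == 6) ? 6 : 26;
  int off6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  int cur = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        const int id0 = idx3(i, j, k, d);
        if (!mask[id0] || lab[id0] != 0) continue;
        ++cur;
        std::queue<std::array<int, 3>> q;
        q.push({i, j, k}); lab[id0] = cur;
        while (!q.empty()) {
          auto p = q.front(); q.pop();
          for (int m = 0; m < nn; ++m) {
            const int* o = (connectivity == 6) ? off6[m] : off[m];
            const int i2 = p[0] + o[0], j2 = p[1] + o[1], k2 = p[2] + o[2];
            if (!inb(i2, j2, k2, d)) continue;
            const int id2 = idx3(i2, j2, k2, d);
            if (!mask[id2] || lab[id2] != 0) continue;
            lab[id2] = cur; q.push({i2, j2, k2});
          }
        }
      }
  return lab;
}

// ---- surface-nets mesh of a binary mask -----------------------------------
// Dual-contouring surface: one vertex per mixed 2x2x2 voxel block (centroid of
// its in/out edge-crossing midpoints); one quad per boundary lattice edge,
// wound so normals point outward. Closed and orientation-consistent by
// construction. Returns area, enclosed volume, and max pairwise vertex
// distances in 3D and in each axis-aligned projection plane.
// [[Rcpp::export]]
List cpp_surface_mesh(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int pd[3] = {d[0] + 2, d[1] + 2, d[2] + 2};
  std::vector<char> m((size_t)pd[0] * pd[1] * pd[2], 0);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i)
        if (mask[idx3(i, j, k, d)])
          m[idx3(i + 1, j + 1, k + 1, pd)] = 1;

  auto mval = [&](int i, int j, int k) -> char {
    return m[idx3(i, j, k, pd)];
  };

  // vertex per mixed dual cell (block of voxels c..c+1 per axis)
  std::unordered_map<long long, int> cell_id;
  std::vector<double> vx, vy, vz;
  auto cell_vertex = [&](int ci, int cj, int ck) -> int {
    const long long key = ((long long)ci * pd[1] + cj) * pd[2] + ck;
    auto it = cell_id.find(key);
    if (it != cell_id.end()) return it->second;
    double sx = 0, sy = 0, sz = 0; int np = 0;
    for (int a = ci; a <= ci + 1; ++a)
      for (int b = cj; b <= cj + 1; ++b)
        for (int c = ck; c <= ck + 1; ++c) {
          const char v0 = mval(a, b, c);
          if (a + 1 <= ci + 1 && mval(a + 1, b, c) != v0) {
            sx += a + 0.5; sy += b; sz += c; ++np;
          }
          if (b + 1 <= cj + 1 && mval(a, b + 1, c) != v0) {
            sx += a; sy += b + 0.5; sz += c; ++np;
          }
          if (c + 1 <= ck + 1 && mval(a, b, c + 1) != v0) {
            sx += a; sy += b; sz += c + 0.5; ++np;
          }
        }
    const int id = (int)vx.size();
    vx.push_back(sx / np); vy.push_back(sy / np); vz.push_back(sz / np);
    cell_id[key] = id;
    return id;
  };

  double area = 0.0, svol = 0.0;
  // quad cell offsets around an edge along each axis, counterclockwise about
  // the positive axis direction
  // same counterclockwise pattern for every axis under the cyclic coordinate
  // assignment x-edge -> (y, z), y-edge -> (z, x), z-edge -> (x, y)
  const int qoff[4][2] = {{-1, -1}, {0, -1}, {0, 0}, {-1, 0}};

  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  for (int k = 0; k < pd[2] - 1; ++k)
    for (int j = 0; j < pd[1] - 1; ++j)
      for (int i = 0; i < pd[0] - 1; ++i) {
        for (int ax = 0; ax < 3; ++ax) {
          const int i2 = i + (ax == 0), j2 = j + (ax == 1), k2 = k + (ax == 2);
          if (i2 >= pd[0] || j2 >= pd[1] || k2 >= pd[2]) continue;
          const char a0 = mval(i, j, k), a1 = mval(i2, j2, k2);
          if (a0 == a1) continue;
          int vid[4];
          for (int q = 0; q < 4; ++q) {
            int ci = i, cj = j, ck = k;
            if (ax == 0) { cj += qoff[q][0]; ck += qoff[q][1]; }
            else if (ax == 1) { ck += qoff[q][0]; ci += qoff[q][1]; }
            else { ci += qoff[q][0]; cj += qoff[q][1]; }
            vid[q] = cell_vertex(ci, cj, ck);
          }
          // orient outward: if a0 is inside, normal points along +axis and the
          // counterclockwise order is correct; else reverse
          if (!a0) { std::swap(vid[0], vid[3]); std::swap(vid[1], vid[2]); }
          // two triangles (0,1,2) and (0,2,3), physical coordinates
          for (int t = 0; t < 2; ++t) {
            const int ia = vid[0], ib = vid[t + 1], ic = vid[t + 2];
            const double ax0 = (vx[ia] - 1) * hx, ay0 = (vy[ia] - 1) * hy,
                         az0 = (vz[ia] - 1) * hz;
            const double bx = (vx[ib] - 1) * hx, by = (vy[ib] - 1) * hy,
                         bz = (vz[ib] - 1) * hz;
            const double cx = (vx[ic] - 1) * hx, cy = (vy[ic] - 1) * hy,
                         cz = (vz[ic] - 1) * hz;
            const double ux = bx - ax0, uy = by - ay0, uz = bz - az0;
            const double wx = cx - ax0, wy = cy - ay0, wz = cz - az0;
            const double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz,
                         nz = ux * wy - uy * wx;
            area += 0.5 * std::sqrt(nx * nx + ny * ny + nz * nz);
            svol += (ax0 * (by * cz - bz * cy) - ay0 * (bx * cz - bz * cx) +
                     az0 * (bx * cy - by * cx)) / 6.0;
          }
        }
      }

  // max pairwise distances over unique vertices (physical coordinates)
  const int nv = (int)vx.size();
  double d3 = 0, dxy = 0, dzy = 0, dzx = 0;
  for (int a = 0; a < nv; ++a) {
    const double xa = (vx[a] - 1) * hx, ya = (vy[a] - 1) * hy,
                 za = (vz[a] - 1) * hz;
    for (int b = a + 1; b < nv; ++b) {
      const double dx = xa - (vx[b] - 1) * hx;
      const double dy = ya - (vy[b] - 1) * hy;
      const double dz = za - (vz[b] - 1) * hz;
      const double q3 = dx * dx + dy * dy + dz * dz;
      if (q3 > d3) d3 = q3;
      const double qxy = dx * dx + dy * dy;
      if (qxy > dxy) dxy = qxy;
      const double qzy = dz * dz + dy * dy;
      if (qzy > dzy) dzy = qzy;
      const double qzx = dz * dz + dx * dx;
      if (qzx > dzx) dzx = qzx;
    }
  }

  NumericMatrix verts(nv, 3);
  for (int a = 0; a < nv; ++a) {
    verts(a, 0) = (vx[a] - 1) * hx;
    verts(a, 1) = (vy[a] - 1) * hy;
    verts(a, 2) = (vz[a] - 1) * hz;
  }
  return List::create(
    _["area"] = area, _["volume"] = std::fabs(svol),
    _["signed_volume"] = svol,
    _["diameter3d"] = std::sqrt(d3), _["diameter_xy"] = std::sqrt(dxy),
    _["diameter_zy"] = std::sqrt(dzy), _["diameter_zx"] = std::sqrt(dzx),
    _["n_vertices"] = nv, _["vertices"] = verts);
}
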