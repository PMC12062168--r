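#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discretized volumes are passed as an integer vector in R column-major
// order: 0 marks voxels outside the ROI, 1..ng are gray levels inside.
// The 13 unique 3D displacement directions (half of the 26-neighborhood).
static const int DIR[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

static inline bool inside(int i, int j, int k, int nx, int ny, int nz) {
  return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
}

// Gray level co-occurrence matrix, symmetric, distance 1, merged over the
// 13 directions (IBSI "merged" aggregation).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector g, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix P(ng, ng);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = g[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        for (int d = 0; d < 13; ++d) {
          int ii = i + DIR[d][0], jj = j + DIR[d][1], kk = k + DIR[d][2];
          if (!inside(ii, jj, kk, nx, ny, nz)) continue;
          int b = g[idx3(ii, jj, kk, nx, ny)];
          if (b == 0) continue;
          P(a - 1, b - 1) += 1.0;
          P(b - 1, a - 1) += 1.0;
        }
      }
  return P;
}

// Gray level run length matrix, merged over the 13 directions.
// A run is a maximal straight segment of in-ROI voxels sharing one level.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector g, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = std::max(nx, std::max(ny, nz));
  NumericMatrix P(ng, lmax);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR[d][0], dy = DIR[d][1], dz = DIR[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = g[idx3(i, j, k, nx, ny)];
          if (a == 0) continue;
          // start of a run: predecessor along -d absent or different
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (inside(pi, pj, pk, nx, ny, nz) &&
              g[idx3(pi, pj, pk, nx, ny)] == a) continue;
          int len = 1;
          int ci = i + dx, cj = j + dy, ck = k + dz;
          while (inside(ci, cj, ck, nx, ny, nz) &&
                 g[idx3(ci, cj, ck, nx, ny)] == a) {
            ++len; ci += dx; cj += dy; ck += dz;
          }
          P(a - 1, len - 1) += 1.0;
        }
  }
  return P;
}

// Gray level size zones: 26-connected components of equal level.
// Returns a two-column matrix (level, size), one row per zone; kept as a
// zone list rather than the (possibly huge) Ng x Smax matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector g, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones; // (level, size)
  std::vector<int> stack;
  int smax = 1;
  for (int v = 0; v < n; ++v) {
    if (g[v] == 0 || seen[v]) continue;
    int lev = g[v];
    int size = 0;
    stack.clear();
    stack.push_back(v);
    seen[v] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      ++size;
      int ui = u % nx, uj = (u / nx) % ny, uk = u / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = ui + di, jj = uj + dj, kk = uk + dk;
            if (!inside(ii, jj, kk, nx, ny, nz)) continue;
            int w = idx3(ii, jj, kk, nx, ny);
            if (!seen[w] && g[w] == lev) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > smax) smax = size;
  }
  IntegerMatrix out(zones.size(), 2);
  for (size_t z = 0; z < zones.size(); ++z) {
    out(z, 0) = zones[z].first;
    out(z, 1) = zones[z].second;
  }
  return out;
}

// NGTDM: per level i, n_i = number of ROI voxels at level i that have at
// least one ROI neighbor, s_i = sum over those voxels of |i - mean of the
// 26-neighborhood levels (ROI voxels only)|.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector g, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // columns: n_i, s_i
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = g[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (!inside(ii, jj, kk, nx, ny, nz)) continue;
              int b = g[idx3(ii, jj, kk, nx, ny)];
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs(a - sum / cnt);
      }
  return out;
}

// GLDM: dependence = number of 26-neighbors with |level difference| <= alpha.
// P(i, d + 1) counts ROI voxels of level i with dependence d (d = 0..26).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector g, IntegerVector dim, int ng, int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix P(ng, 27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = g[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        int dep = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (!inside(ii, jj, kk, nx, ny, nz)) continue;
              int b = g[idx3(ii, jj, kk, nx, ny)];
              if (b > 0 && std::abs(b - a) <= alpha) ++dep;
            }
        P(a - 1, dep) += 1.0;
      }
  return P;
}

// ---- mesh surface via marching tetrahedra ---------------------------------

struct Vec3 { double x, y, z; };

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  Vec3 r; r.x = a.x - b.x; r.y = a.y - b.y; r.z = a.z - b.z; return r;
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  Vec3 r;
  r.x = a.y * b.z - a.z * b.y;
  r.y = a.z * b.x - a.x * b.z;
  r.z = a.x * b.y - a.y * b.x;
  return r;
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vmid(const Vec3 &a, const Vec3 &b) {
  Vec3 r; r.x = 0.5 * (a.x + b.x); r.y = 0.5 * (a.y + b.y);
  r.z = 0.5 * (a.z + b.z); return r;
}

// Accumulate one triangle: area, and signed volume by the divergence
// theorem with a consistent outward orientation. `ref` is a point on the
// inside of the surface near this face; the triangle is flipped so its
// normal points away from it before the origin-based volume term is added.
static void add_tri(Vec3 p0, Vec3 p1, Vec3 p2,
                    const Vec3 &ref, double &area, double &vol) {
  Vec3 u = vsub(p1, p0), v = vsub(p2, p0);
  Vec3 nrm = vcross(u, v);
  Vec3 cen; cen.x = (p0.x + p1.x + p2.x) / 3.0 - ref.x;
  cen.y = (p0.y + p1.y + p2.y) / 3.0 - ref.y;
  cen.z = (p0.z + p1.z + p2.z) / 3.0 - ref.z;
  area += 0.5 * std::sqrt(vdot(nrm, nrm));
  if (vdot(nrm, cen) < 0.0) { Vec3 t = p1; p1 = p2; p2 = t; }
  vol += vdot(p0, vcross(p1, p2)) / 6.0;
}

// 6-tetrahedra decomposition of the unit cube (corner ids 0..7 with
// corner c = (c&1, (c>>1)&1, (c>>2)&1)).
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

static inline Vec3 vlerp(const Vec3 &a, const Vec3 &b, double fa, double fb,
                         double iso) {
  double t = (fb - fa == 0.0) ? 0.5 : (iso - fa) / (fb - fa);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  Vec3 r;
  r.x = a.x + t * (b.x - a.x);
  r.y = a.y + t * (b.y - a.y);
  r.z = a.z + t * (b.z - a.z);
  return r;
}

// Surface area (mm^2) and mesh volume (mm^3) of a binary mask by marching
// tetrahedra at isolevel 0.5 on a 3x3x3 box-smoothed occupancy field with
// linearly interpolated edge crossings (the smoothing suppresses the
// staircase artifact of meshing a raw binary field). The field vanishes
// outside the padded grid, so the surface is closed.
// [[Rcpp::export]]
NumericVector cpp_mesh(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // smoothed occupancy on a grid padded by 2 voxels each side
  int px = nx + 4, py = ny + 4, pz = nz + 4;
  std::vector<double> F((size_t)px * py * pz, 0.0);
  for (int k = -2; k < nz + 2; ++k)
    for (int j = -2; j < ny + 2; ++j)
      for (int i = -2; i < nx + 2; ++i) {
        double s = 0.0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (inside(ii, jj, kk, nx, ny, nz) &&
                  mask[idx3(ii, jj, kk, nx, ny)]) s += 1.0;
            }
        F[(size_t)(i + 2) + px * ((j + 2) + (size_t)py * (k + 2))] = s / 27.0;
      }
  const double iso = 0.5;
  double area = 0.0, vol = 0.0;
  for (int k = 0; k < pz - 1; ++k)
    for (int j = 0; j < py - 1; ++j)
      for (int i = 0; i < px - 1; ++i) {
        double f[8];
        Vec3 pos[8];
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1),
              ck = k + ((c >> 2) & 1);
          f[c] = F[(size_t)ci + px * (cj + (size_t)py * ck)];
          nin += (f[c] > iso);
          pos[c].x = (ci - 2) * sx;
          pos[c].y = (cj - 2) * sy;
          pos[c].z = (ck - 2) * sz;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int vin[4], nvi = 0;
          for (int m = 0; m < 4; ++m) {
            vin[m] = f[T[m]] > iso;
            nvi += vin[m];
          }
          if (nvi == 0 || nvi == 4) continue;
          // reference point on the inside: centroid of inside vertices
          Vec3 ref; ref.x = ref.y = ref.z = 0.0;
          int nr = 0;
          for (int m = 0; m < 4; ++m)
            if (vin[m]) {
              ref.x += pos[T[m]].x; ref.y += pos[T[m]].y;
              ref.z += pos[T[m]].z; ++nr;
            }
          ref.x /= nr; ref.y /= nr; ref.z /= nr;
          if (nvi == 1 || nvi == 3) {
            int lone = -1;
            for (int m = 0; m < 4; ++m)
              if ((nvi == 1 && vin[m]) || (nvi == 3 && !vin[m])) lone = m;
            Vec3 mp[3]; int c = 0;
            for (int m = 0; m < 4; ++m)
              if (m != lone)
                mp[c++] = vlerp(pos[T[lone]], pos[T[m]], f[T[lone]],
                                f[T[m]], iso);
            add_tri(mp[0], mp[1], mp[2], ref, area, vol);
          } else { // 2 in / 2 out: quad split into two triangles
            int a[2], b[2], ca = 0, cb = 0;
            for (int m = 0; m < 4; ++m) {
              if (vin[m]) a[ca++] = m; else b[cb++] = m;
            }
            Vec3 m00 = vlerp(pos[T[a[0]]], pos[T[b[0]]], f[T[a[0]]],
                             f[T[b[0]]], iso);
            Vec3 m01 = vlerp(pos[T[a[0]]], pos[T[b[1]]], f[T[a[0]]],
                             f[T[b[1]]], iso);
            Vec3 m10 = vlerp(pos[T[a[1]]], pos[T[b[0]]], f[T[a[1]]],
                             f[T[b[0]]], iso);
            Vec3 m11 = vlerp(pos[T[a[1]]], pos[T[b[1]]], f[T[a[1]]],
                             f[T[b[1]]], iso);
            add_tri(m00, m01, m11, ref, area, vol);
            add_tri(m00, m11, m10, ref, area, vol);
          }
        }
      }
  if (vol < 0) vol = -vol;
  return NumericVector::create(area, vol);
}

// Maximum pairwise distances between surface voxels: overall (3D) and
// within axial (fixed z), coronal (fixed y) and sagittal (fixed x) planes.
// Surface voxels are ROI voxels with at least one 6-neighbor outside.
// [[Rcpp::export]]
NumericVector cpp_max_diameters(LogicalVector mask, IntegerVector dim,
                                NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<int> xi, yi, zi;
  static const int N6[6][3] = {
    {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[idx3(i, j, k, nx, ny)]) continue;
        bool surf = false;
        for (int d = 0; d < 6 && !surf; ++d) {
          int ii = i + N6[d][0], jj = j + N6[d][1], kk = k + N6[d][2];
          if (!inside(ii, jj, kk, nx, ny, nz) ||
              !mask[idx3(ii, jj, kk, nx, ny)]) surf = true;
        }
        if (surf) { xi.push_back(i); yi.push_back(j); zi.push_back(k); }
      }
  size_t n = xi.size();
  double d3 = 0.0, dslice = 0.0, dcol = 0.0, drow = 0.0;
  for (size_t a = 0; a + 1 < n; ++a)
    for (size_t b = a + 1; b < n; ++b) {
      double dx = (xi[a] - xi[b]) * sx;
      double dy = (yi[a] - yi[b]) * sy;
      double dz = (zi[a] - zi[b]) * sz;
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd > d3) d3 = dd;
      if (zi[a] == zi[b] && dx * dx + dy * dy > dslice)
        dslice = dx * dx + dy * dy;
      if (yi[a] == yi[b] && dx * dx + dz * dz > dcol)
        dcol = dx * dx + dz * dz;
      if (xi[a] == xi[b] && dy * dy + dz * dz > drow)
        drow = dy * dy + dz * dz;
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dslice),
                               std::sqrt(dcol), std::sqrt(drow));
}
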