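#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Arrays are R column-major with dim (ny, nx, nz):
// linear index = y + ny * (x + nx * z), 0-based here.

static inline long idx3(int y, int x, int z, int ny, int nx) {
  return (long)y + (long)ny * ((long)x + (long)nx * (long)z);
}

// ---------------------------------------------------------------------------
// 26-connected component labeling (union-find with path compression)
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  int root = i;
  while (parent[root] != root) root = parent[root];
  while (parent[i] != root) { int nxt = parent[i]; parent[i] = root; i = nxt; }
  return root;
}

// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector fg, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const long n = (long)ny * nx * nz;
  if ((long)fg.size() != n) stop("foreground length does not match dims");

  // map foreground voxels to compact ids
  std::vector<int> id(n, -1);
  int nfg = 0;
  for (long i = 0; i < n; ++i) if (fg[i]) id[i] = nfg++;
  std::vector<int> parent(nfg);
  for (int i = 0; i < nfg; ++i) parent[i] = i;

  // half-neighborhood: offsets strictly preceding in scan order
  int offs[13][3]; // dy, dx, dz
  int no = 0;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dz == 0 && (dx > 0 || (dx == 0 && dy >= 0))) continue;
        if (dz == 0 && dx == 0 && dy == 0) continue;
        offs[no][0] = dy; offs[no][1] = dx; offs[no][2] = dz; ++no;
      }

  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        long i = idx3(y, x, z, ny, nx);
        if (!fg[i]) continue;
        for (int k = 0; k < no; ++k) {
          int yy = y + offs[k][0], xx = x + offs[k][1], zz = z + offs[k][2];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0) continue;
          long j = idx3(yy, xx, zz, ny, nx);
          if (!fg[j]) continue;
          int ra = uf_find(parent, id[i]), rb = uf_find(parent, id[j]);
          if (ra != rb) parent[ra] = rb;
        }
      }

  // contiguous labels 1..N in first-encounter order
  std::vector<int> lab(nfg, 0);
  int next = 0;
  IntegerVector out(n, 0);
  for (long i = 0; i < n; ++i) {
    if (id[i] < 0) continue;
    int r = uf_find(parent, id[i]);
    if (lab[r] == 0) lab[r] = ++next;
    out[i] = lab[r];
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform, anisotropic sampling
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, per axis)
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, double step, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + step * step * q * q;
    double s;
    while (true) {
      double fv = f[v[k]] + step * step * v[k] * v[k];
      s = (fq - fv) / (2.0 * step * step * (q - v[k]));
      if (k > 0 && s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = step * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// distance (um) from every voxel to the nearest TRUE voxel
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector obj, IntegerVector dims, NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const long n = (long)ny * nx * nz;
  const double sy = spacing[0], sx = spacing[1], sz = spacing[2];
  // large finite stand-in for "no object in this line": keeps the
  // lower-envelope parabola comparisons well-defined
  const double BIG = 1e15;
  std::vector<double> g(n);
  for (long i = 0; i < n; ++i) g[i] = obj[i] ? 0.0 : BIG;

  std::vector<double> line;
  // along y
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = g[idx3(y, x, z, ny, nx)];
      dt1d(line, sy, ny);
      for (int y = 0; y < ny; ++y) g[idx3(y, x, z, ny, nx)] = line[y];
    }
  // along x
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) line[x] = g[idx3(y, x, z, ny, nx)];
      dt1d(line, sx, nx);
      for (int x = 0; x < nx; ++x) g[idx3(y, x, z, ny, nx)] = line[x];
    }
  // along z
  if (nz > 1) {
    line.resize(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) line[z] = g[idx3(y, x, z, ny, nx)];
        dt1d(line, sz, nz);
        for (int z = 0; z < nz; ++z) g[idx3(y, x, z, ny, nx)] = line[z];
      }
  }

  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Iso-surface area by marching tetrahedra
// ---------------------------------------------------------------------------

struct P3 { double x, y, z; };

static inline P3 vlerp(const P3& a, const P3& b, double va, double vb, double level) {
  double t = (vb == va) ? 0.5 : (level - va) / (vb - va);
  if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
  P3 p; p.x = a.x + t * (b.x - a.x); p.y = a.y + t * (b.y - a.y); p.z = a.z + t * (b.z - a.z);
  return p;
}

static inline double tri_area(const P3& a, const P3& b, const P3& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// area contributed by one tetrahedron (Bourke's case table, winding ignored)
static double polygonise_tet(const P3 p[4], const double v[4], double level) {
  int code = 0;
  if (v[0] >= level) code |= 1;
  if (v[1] >= level) code |= 2;
  if (v[2] >= level) code |= 4;
  if (v[3] >= level) code |= 8;
  P3 a, b, c, d;
  switch (code) {
  case 0x00: case 0x0F:
    return 0.0;
  case 0x01: case 0x0E:
    a = vlerp(p[0], p[1], v[0], v[1], level);
    b = vlerp(p[0], p[2], v[0], v[2], level);
    c = vlerp(p[0], p[3], v[0], v[3], level);
    return tri_area(a, b, c);
  case 0x02: case 0x0D:
    a = vlerp(p[1], p[0], v[1], v[0], level);
    b = vlerp(p[1], p[3], v[1], v[3], level);
    c = vlerp(p[1], p[2], v[1], v[2], level);
    return tri_area(a, b, c);
  case 0x03: case 0x0C:
    a = vlerp(p[0], p[3], v[0], v[3], level);
    b = vlerp(p[0], p[2], v[0], v[2], level);
    c = vlerp(p[1], p[3], v[1], v[3], level);
    d = vlerp(p[1], p[2], v[1], v[2], level);
    return tri_area(a, b, c) + tri_area(c, b, d);
  case 0x04: case 0x0B:
    a = vlerp(p[2], p[0], v[2], v[0], level);
    b = vlerp(p[2], p[1], v[2], v[1], level);
    c = vlerp(p[2], p[3], v[2], v[3], level);
    return tri_area(a, b, c);
  case 0x05: case 0x0A:
    a = vlerp(p[0], p[1], v[0], v[1], level);
    b = vlerp(p[2], p[3], v[2], v[3], level);
    c = vlerp(p[0], p[3], v[0], v[3], level);
    d = vlerp(p[1], p[2], v[1], v[2], level);
    return tri_area(a, b, c) + tri_area(a, d, b);
  case 0x06: case 0x09:
    a = vlerp(p[0], p[1], v[0], v[1], level);
    b = vlerp(p[1], p[3], v[1], v[3], level);
    c = vlerp(p[2], p[3], v[2], v[3], level);
    d = vlerp(p[0], p[2], v[0], v[2], level);
    return tri_area(a, b, c) + tri_area(a, c, d);
  case 0x07: case 0x08:
    a = vlerp(p[3], p[0], v[3], v[0], level);
    b = vlerp(p[3], p[2], v[3], v[2], level);
    c = vlerp(p[3], p[1], v[3], v[1], level);
    return tri_area(a, b, c);
  }
  return 0.0;
}

// corner offsets (dx, dy, dz), standard marching-cubes vertex order
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};
// six tetrahedra sharing the 0-6 diagonal
static const int TET[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector vol, IntegerVector dims,
                           NumericVector spacing, double level) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double sy = spacing[0], sx = spacing[1], sz = spacing[2];
  double area = 0.0;
  double cv[8];
  P3 cp[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int x = 0; x + 1 < nx; ++x)
      for (int y = 0; y + 1 < ny; ++y) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + CORNER[c][0], cyy = y + CORNER[c][1], cz = z + CORNER[c][2];
          double v = vol[idx3(cyy, cx, cz, ny, nx)];
          cv[c] = v;
          if (v >= level) anyAbove = true; else anyBelow = true;
          cp[c].x = cx * sx; cp[c].y = cyy * sy; cp[c].z = cz * sz;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tp[4]; double tv[4];
          for (int k = 0; k < 4; ++k) { tp[k] = cp[TET[t][k]]; tv[k] = cv[TET[t][k]]; }
          area += polygonise_tet(tp, tv, level);
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Exact two-sided permutation p-value for the rank correlation
// ---------------------------------------------------------------------------

// rx, ry: mid-ranks. Enumerates all distinct orderings of ry.
// [[Rcpp::export]]
double cpp_perm_pvalue(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (ry.size() != n) stop("length mismatch");
  std::vector<double> a(rx.begin(), rx.end()), b(ry.begin(), ry.end());
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sa = 0, sb = 0;
  for (int i = 0; i < n; ++i) {
    a[i] -= ma; b[i] -= mb;
    sa += a[i] * a[i]; sb += b[i] * b[i];
  }
  if (sa <= 0 || sb <= 0) stop("constant ranks: correlation undefined");
  double obs = 0;
  for (int i = 0; i < n; ++i) obs += a[i] * b[i];
  obs = std::fabs(obs);

  std::sort(b.begin(), b.end());
  long total = 0, hits = 0;
  const double eps = 1e-9 * (sa > sb ? sa : sb) + 1e-12;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += a[i] * b[i];
    if (std::fabs(s) >= obs - eps) ++hits;
    ++total;
  } while (std::next_permutation(b.begin(), b.end()));
  return (double)hits / (double)total;
}
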