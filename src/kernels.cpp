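// Low-level 3D voxel kernels shared by the segmentation, nuclei, morphometry
// and radial-line modules. All arrays are column-major with dim = (nx, ny, nz)
// and 0-based linear index i = x + nx*(y + ny*z); R wrappers own the 1-based
// conversion. Distances are physical (per-axis spacing in micrometres).

#include <Rcpp.h>
#include <array>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Grid {
  int nx, ny, nz;
  explicit Grid(const IntegerVector &dim)
      : nx(dim[0]), ny(dim[1]), nz(dim[2]) {}
  std::size_t n() const {
    return static_cast<std::size_t>(nx) * ny * nz;
  }
  int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
  void coords(int i, int &x, int &y, int &z) const {
    x = i % nx;
    y = (i / nx) % ny;
    z = i / (nx * ny);
  }
  bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// Neighbourhood offsets; connectivity 6 (faces) or 26 (full cube).
std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Sentinel squared distance standing in for "no background reachable yet";
// large enough to dominate any physical squared distance, small enough for
// exact double arithmetic in the envelope computation.
const double BIG_SQ = 1e30;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher) with
// physical sample spacing w; positions are index units, weights w^2.
void edt_1d(const double *f, double *d, int n, double w,
            std::vector<int> &v, std::vector<double> &zbuf) {
  v.resize(n);
  zbuf.resize(n + 1);
  int k = 0;
  v[0] = 0;
  zbuf[0] = -INF;
  zbuf[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
          (2.0 * w2 * (q - p));
      if (s <= zbuf[k]) --k;
      else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    d[q] = f[v[k]] + w2 * (q - v[k]) * (q - v[k]);
  }
}

}  // namespace

// Euclidean distance (physical units) from each TRUE voxel to the nearest
// FALSE voxel; 0 on FALSE voxels. Anisotropy-aware via per-axis spacing.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  Grid g(dim);
  std::size_t n = g.n();
  NumericVector out(n);
  for (std::size_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG_SQ : 0.0;

  std::vector<int> v;
  std::vector<double> zbuf;
  // pass along x
  {
    std::vector<double> f(g.nx), d(g.nx);
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y) {
        int base = g.idx(0, y, z);
        for (int x = 0; x < g.nx; ++x) f[x] = out[base + x];
        edt_1d(f.data(), d.data(), g.nx, spacing[0], v, zbuf);
        for (int x = 0; x < g.nx; ++x) out[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(g.ny), d(g.ny);
    for (int z = 0; z < g.nz; ++z)
      for (int x = 0; x < g.nx; ++x) {
        for (int y = 0; y < g.ny; ++y) f[y] = out[g.idx(x, y, z)];
        edt_1d(f.data(), d.data(), g.ny, spacing[1], v, zbuf);
        for (int y = 0; y < g.ny; ++y) out[g.idx(x, y, z)] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(g.nz), d(g.nz);
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        for (int z = 0; z < g.nz; ++z) f[z] = out[g.idx(x, y, z)];
        edt_1d(f.data(), d.data(), g.nz, spacing[2], v, zbuf);
        for (int z = 0; z < g.nz; ++z) out[g.idx(x, y, z)] = d[z];
      }
  }
  for (std::size_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

namespace {
// reflect an out-of-range index into [0, n) (half-sample symmetric padding)
inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}
}  // namespace

// Separable moving-average (box mean) with mirrored padding; radius per axis.
// [[Rcpp::export]]
NumericVector cpp_box_mean(NumericVector x, IntegerVector dim,
                           IntegerVector radius) {
  Grid g(dim);
  std::size_t n = g.n();
  NumericVector cur = clone(x);
  NumericVector nxt(n);
  int dims[3] = {g.nx, g.ny, g.nz};
  for (int axis = 0; axis < 3; ++axis) {
    int r = radius[axis];
    if (r <= 0) continue;
    int len = dims[axis];
    int stride = (axis == 0) ? 1 : (axis == 1 ? g.nx : g.nx * g.ny);
    int nlines = static_cast<int>(n) / len;
    std::vector<double> line(len);
    for (int l = 0; l < nlines; ++l) {
      // compute base offset of this line
      int base;
      if (axis == 0) {
        base = l * g.nx;
      } else if (axis == 1) {
        int z = l / g.nx, x0 = l % g.nx;
        base = g.idx(x0, 0, z);
      } else {
        int y = l / g.nx, x0 = l % g.nx;
        base = g.idx(x0, y, 0);
      }
      for (int i = 0; i < len; ++i) line[i] = cur[base + i * stride];
      // running sum over window [i-r, i+r] with reflection
      double s = 0.0;
      for (int j = -r; j <= r; ++j) s += line[reflect_index(j, len)];
      nxt[base] = s / (2 * r + 1);
      for (int i = 1; i < len; ++i) {
        s += line[reflect_index(i + r, len)];
        s -= line[reflect_index(i - r - 1, len)];
        nxt[base + i * stride] = s / (2 * r + 1);
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Convolve along one axis (0,1,2) with a symmetric kernel, mirrored padding.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector x, IntegerVector dim,
                                NumericVector kernel, int axis) {
  Grid g(dim);
  std::size_t n = g.n();
  NumericVector out(n);
  int dims[3] = {g.nx, g.ny, g.nz};
  int len = dims[axis];
  int stride = (axis == 0) ? 1 : (axis == 1 ? g.nx : g.nx * g.ny);
  int nk = kernel.size();
  int r = (nk - 1) / 2;
  int nlines = static_cast<int>(n) / len;
  std::vector<double> line(len);
  for (int l = 0; l < nlines; ++l) {
    int base;
    if (axis == 0) {
      base = l * g.nx;
    } else if (axis == 1) {
      int z = l / g.nx, x0 = l % g.nx;
      base = g.idx(x0, 0, z);
    } else {
      int y = l / g.nx, x0 = l % g.nx;
      base = g.idx(x0, y, 0);
    }
    for (int i = 0; i < len; ++i) line[i] = x[base + i * stride];
    for (int i = 0; i < len; ++i) {
      double s = 0.0;
      for (int j = -r; j <= r; ++j)
        s += kernel[j + r] * line[reflect_index(i + j, len)];
      out[base + i * stride] = s;
    }
  }
  return out;
}

// Label 26- or 6-connected foreground components; labels assigned in
// lexicographic scan order (x fastest) for determinism.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  Grid g(dim);
  std::size_t n = g.n();
  IntegerVector lab(n);
  auto off = neighbour_offsets(connectivity);
  std::vector<int> stack;
  int next = 0;
  for (std::size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(static_cast<int>(i));
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int x, y, z;
      g.coords(cur, x, y, z);
      for (const auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (!g.inside(xx, yy, zz)) continue;
        int j = g.idx(xx, yy, zz);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Fill background cavities not connected (6-conn) to the grid boundary.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::size_t n = g.n();
  std::vector<char> outside(n, 0);
  auto off = neighbour_offsets(6);
  std::vector<int> stack;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        if (x != 0 && x != g.nx - 1 && y != 0 && y != g.ny - 1 && z != 0 &&
            z != g.nz - 1)
          continue;
        int i = g.idx(x, y, z);
        if (!mask[i] && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int x, y, z;
    g.coords(cur, x, y, z);
    for (const auto &o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (!g.inside(xx, yy, zz)) continue;
      int j = g.idx(xx, yy, zz);
      if (!mask[j] && !outside[j]) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  LogicalVector out(n);
  for (std::size_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

namespace {
struct QItem {
  double v;
  std::int64_t ord;  // insertion order; earlier wins among equal v
  int idx;
};
struct QLess {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.v != b.v) return a.v < b.v;  // max-heap on v
    return a.ord > b.ord;              // FIFO among ties
  }
};
using MaxQueue = std::priority_queue<QItem, std::vector<QItem>, QLess>;
}  // namespace

// Grayscale morphological reconstruction by dilation of `marker` under
// `ceiling`, restricted to `domain` (values outside the domain are ignored).
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker,
                                       NumericVector ceiling,
                                       LogicalVector domain,
                                       IntegerVector dim, int connectivity) {
  Grid g(dim);
  std::size_t n = g.n();
  NumericVector out(n);
  auto off = neighbour_offsets(connectivity);
  MaxQueue q;
  std::int64_t ord = 0;
  for (std::size_t i = 0; i < n; ++i) {
    if (!domain[i]) { out[i] = -INF; continue; }
    out[i] = std::min(marker[i], ceiling[i]);
    q.push({out[i], ord++, static_cast<int>(i)});
  }
  while (!q.empty()) {
    QItem it = q.top();
    q.pop();
    if (it.v < out[it.idx]) continue;  // stale
    int x, y, z;
    g.coords(it.idx, x, y, z);
    for (const auto &o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (!g.inside(xx, yy, zz)) continue;
      int j = g.idx(xx, yy, zz);
      if (!domain[j]) continue;
      double nv = std::min(out[it.idx], ceiling[j]);
      if (nv > out[j]) {
        out[j] = nv;
        q.push({nv, ord++, j});
      }
    }
  }
  return out;
}

// Label regional-maximum plateaus of f within domain (26-conn plateaus);
// a plateau is a maximum iff no member has a strictly greater in-domain
// neighbour. Returns labels 1..k in scan order, 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector f, LogicalVector domain,
                                  IntegerVector dim, int connectivity) {
  Grid g(dim);
  std::size_t n = g.n();
  IntegerVector lab(n);
  auto off = neighbour_offsets(connectivity);
  std::vector<int> stack, members;
  int next = 0;
  std::vector<char> visited(n, 0);
  for (std::size_t i = 0; i < n; ++i) {
    if (!domain[i] || visited[i]) continue;
    // flood the plateau of equal value containing i
    double val = f[i];
    bool is_max = true;
    members.clear();
    stack.clear();
    visited[i] = 1;
    stack.push_back(static_cast<int>(i));
    members.push_back(static_cast<int>(i));
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int x, y, z;
      g.coords(cur, x, y, z);
      for (const auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (!g.inside(xx, yy, zz)) continue;
        int j = g.idx(xx, yy, zz);
        if (!domain[j]) continue;
        if (f[j] > val) is_max = false;
        else if (f[j] == val && !visited[j]) {
          visited[j] = 1;
          stack.push_back(j);
          members.push_back(j);
        }
      }
    }
    if (is_max) {
      ++next;
      for (int m : members) lab[m] = next;
    }
  }
  return lab;
}

// Seeded watershed by priority flooding on a height field (flooded in order
// of decreasing height, i.e. basins grow outward from the deepest points of
// the negated field). Ties broken FIFO for bit-reproducibility.
// [[Rcpp::export]]
IntegerVector cpp_watershed(LogicalVector mask, NumericVector height,
                            IntegerVector seeds, IntegerVector dim,
                            int connectivity) {
  Grid g(dim);
  std::size_t n = g.n();
  IntegerVector lab(n);
  auto off = neighbour_offsets(connectivity);
  MaxQueue q;
  std::int64_t ord = 0;
  for (std::size_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      q.push({height[i], ord++, static_cast<int>(i)});
    }
  }
  while (!q.empty()) {
    QItem it = q.top();
    q.pop();
    int x, y, z;
    g.coords(it.idx, x, y, z);
    for (const auto &o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (!g.inside(xx, yy, zz)) continue;
      int j = g.idx(xx, yy, zz);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = lab[it.idx];
      q.push({height[j], ord++, j});
    }
  }
  return lab;
}

namespace {
struct Vec3 {
  double x, y, z;
};
inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 lerp(const Vec3 &a, const Vec3 &b, double t) {
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

// accumulate one outward-oriented triangle: area and signed volume
inline void add_tri(Vec3 p1, Vec3 p2, Vec3 p3, const Vec3 &inward,
                    double &area, double &svol) {
  Vec3 nrm = vcross(vsub(p2, p1), vsub(p3, p1));
  Vec3 centroid = {(p1.x + p2.x + p3.x) / 3.0, (p1.y + p2.y + p3.y) / 3.0,
                   (p1.z + p2.z + p3.z) / 3.0};
  if (vdot(nrm, vsub(centroid, inward)) < 0) {
    std::swap(p2, p3);
    nrm = vcross(vsub(p2, p1), vsub(p3, p1));
  }
  double a = 0.5 * std::sqrt(vdot(nrm, nrm));
  area += a;
  svol += vdot(p1, vcross(p2, p3)) / 6.0;
}
}  // namespace

// Isosurface area and enclosed volume of `vol` at `level` via marching
// tetrahedra (six tetrahedra per cell, shared main diagonal). Triangles are
// oriented outward so the divergence-theorem volume is positive for a solid.
// [[Rcpp::export]]
NumericVector cpp_march_measure(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, double level) {
  Grid g(dim);
  double area = 0.0, svol = 0.0;
  // cube corner offsets indexed 0..7
  const int cx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // six tetrahedra sharing diagonal v0-v6
  const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                          {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  double vals[8];
  Vec3 pts[8];
  for (int z = 0; z + 1 < g.nz; ++z)
    for (int y = 0; y + 1 < g.ny; ++y)
      for (int x = 0; x + 1 < g.nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          double v = vol[g.idx(x + cx[c], y + cy[c], z + cz[c])];
          vals[c] = v;
          if (v > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c)
          pts[c] = {(x + cx[c]) * spacing[0], (y + cy[c]) * spacing[1],
                    (z + cz[c]) * spacing[2]};
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0;
          for (int k = 0; k < 4; ++k)
            if (vals[vi[k]] > level) in[nin++] = k;
          if (nin == 0 || nin == 4) continue;
          auto edge_pt = [&](int a, int b) {
            double va = vals[vi[a]], vb = vals[vi[b]];
            double t0 = (level - va) / (vb - va);
            return lerp(pts[vi[a]], pts[vi[b]], t0);
          };
          if (nin == 1 || nin == 3) {
            // single vertex on one side; triangle on its three edges
            int a;
            if (nin == 1) a = in[0];
            else {
              // the single *outside* vertex
              bool used[4] = {false, false, false, false};
              for (int k = 0; k < nin; ++k) used[in[k]] = true;
              a = 0;
              while (used[a]) ++a;
            }
            int others[3], m = 0;
            for (int k = 0; k < 4; ++k)
              if (k != a) others[m++] = k;
            Vec3 q1 = edge_pt(a, others[0]);
            Vec3 q2 = edge_pt(a, others[1]);
            Vec3 q3 = edge_pt(a, others[2]);
            // interior reference point: centroid of inside vertices
            Vec3 inward;
            if (nin == 1) inward = pts[vi[a]];
            else {
              inward = {0, 0, 0};
              for (int k = 0; k < nin; ++k) {
                inward.x += pts[vi[in[k]]].x / nin;
                inward.y += pts[vi[in[k]]].y / nin;
                inward.z += pts[vi[in[k]]].z / nin;
              }
            }
            add_tri(q1, q2, q3, inward, area, svol);
          } else {
            // two inside, two outside: quad split into two triangles
            int a = in[0], b = in[1];
            int outv[2], m = 0;
            for (int k = 0; k < 4; ++k)
              if (k != a && k != b) outv[m++] = k;
            Vec3 q1 = edge_pt(a, outv[0]);
            Vec3 q2 = edge_pt(a, outv[1]);
            Vec3 q3 = edge_pt(b, outv[1]);
            Vec3 q4 = edge_pt(b, outv[0]);
            Vec3 inward = {(pts[vi[a]].x + pts[vi[b]].x) / 2,
                           (pts[vi[a]].y + pts[vi[b]].y) / 2,
                           (pts[vi[a]].z + pts[vi[b]].z) / 2};
            add_tri(q1, q2, q3, inward, area, svol);
            add_tri(q1, q3, q4, inward, area, svol);
          }
        }
      }
  return NumericVector::create(area, std::fabs(svol));
}

// Orientation-weighted boundary-face surface area: every exposed voxel
// face (adjacent in/out pair along an axis) contributes its geometric face
// area times |n_a|, where n is the unit normal estimated by central
// differences of `field` (a smoothed signed distance function) averaged
// over the two voxels sharing the face. Exact for planes of any
// orientation; weights are clamped to <= 1 (a face cannot exceed its own
// area, which also covers degenerate zero-gradient spots).
// [[Rcpp::export]]
double cpp_face_area(NumericVector field, LogicalVector mask,
                     IntegerVector dim, NumericVector spacing) {
  Grid g(dim);
  auto grad = [&](int x, int y, int z, double out[3]) {
    int xm = std::max(x - 1, 0), xp = std::min(x + 1, g.nx - 1);
    int ym = std::max(y - 1, 0), yp = std::min(y + 1, g.ny - 1);
    int zm = std::max(z - 1, 0), zp = std::min(z + 1, g.nz - 1);
    out[0] = (field[g.idx(xp, y, z)] - field[g.idx(xm, y, z)]) /
             ((xp - xm) * spacing[0]);
    out[1] = (field[g.idx(x, yp, z)] - field[g.idx(x, ym, z)]) /
             ((yp - ym) * spacing[1]);
    out[2] = (field[g.idx(x, y, zp)] - field[g.idx(x, y, zm)]) /
             ((zp - zm) * spacing[2]);
  };
  const double face[3] = {spacing[1] * spacing[2], spacing[0] * spacing[2],
                          spacing[0] * spacing[1]};
  double total = 0.0;
  double g1[3], g2[3];
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int i = g.idx(x, y, z);
        for (int a = 0; a < 3; ++a) {
          int xx = x + (a == 0), yy = y + (a == 1), zz = z + (a == 2);
          if (!g.inside(xx, yy, zz)) continue;
          int j = g.idx(xx, yy, zz);
          if (mask[i] == mask[j]) continue;
          grad(x, y, z, g1);
          grad(xx, yy, zz, g2);
          double nx = 0.5 * (g1[0] + g2[0]);
          double ny = 0.5 * (g1[1] + g2[1]);
          double nz = 0.5 * (g1[2] + g2[2]);
          double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
          double comp = (a == 0) ? nx : (a == 1 ? ny : nz);
          double w = (nn > 1e-9) ? std::fabs(comp) / nn : 1.0;
          if (w > 1.0) w = 1.0;
          total += w * face[a];
        }
      }
  return total;
}

// 3D Bresenham digital line between voxel indices (0-based). Returns an
// n x 3 matrix of voxel coordinates; n = max per-axis delta + 1; the path is
// 26-connected, monotone per axis, and includes both endpoints exactly.
// [[Rcpp::export]]
IntegerMatrix cpp_bresenham(IntegerVector p0, IntegerVector p1) {
  int x0 = p0[0], y0 = p0[1], z0 = p0[2];
  int x1 = p1[0], y1 = p1[1], z1 = p1[2];
  int dx = std::abs(x1 - x0), dy = std::abs(y1 - y0), dz = std::abs(z1 - z0);
  int sx = (x1 > x0) ? 1 : (x1 < x0 ? -1 : 0);
  int sy = (y1 > y0) ? 1 : (y1 < y0 ? -1 : 0);
  int sz = (z1 > z0) ? 1 : (z1 < z0 ? -1 : 0);
  int n = std::max(dx, std::max(dy, dz)) + 1;
  IntegerMatrix out(n, 3);
  int x = x0, y = y0, z = z0;
  if (dx >= dy && dx >= dz) {
    int e1 = 2 * dy - dx, e2 = 2 * dz - dx;
    for (int i = 0; i < n; ++i) {
      out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
      if (e1 > 0) { y += sy; e1 -= 2 * dx; }
      if (e2 > 0) { z += sz; e2 -= 2 * dx; }
      e1 += 2 * dy; e2 += 2 * dz;
      x += sx;
    }
  } else if (dy >= dx && dy >= dz) {
    int e1 = 2 * dx - dy, e2 = 2 * dz - dy;
    for (int i = 0; i < n; ++i) {
      out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
      if (e1 > 0) { x += sx; e1 -= 2 * dy; }
      if (e2 > 0) { z += sz; e2 -= 2 * dy; }
      e1 += 2 * dx; e2 += 2 * dz;
      y += sy;
    }
  } else {
    int e1 = 2 * dy - dz, e2 = 2 * dx - dz;
    for (int i = 0; i < n; ++i) {
      out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
      if (e1 > 0) { y += sy; e1 -= 2 * dz; }
      if (e2 > 0) { x += sx; e2 -= 2 * dz; }
      e1 += 2 * dy; e2 += 2 * dx;
      z += sz;
    }
  }
  return out;
}

// For each unit direction, march from `center` (physical coords) in steps of
// `step` micrometres and record the last in-mask voxel before the ray leaves
// the grid. Returns n x 4: voxel (0-based x,y,z) and found flag.
// [[Rcpp::export]]
IntegerMatrix cpp_cast_rays(LogicalVector mask, IntegerVector dim,
                            NumericVector spacing, NumericVector center,
                            NumericMatrix dirs, double step) {
  Grid g(dim);
  int nd = dirs.nrow();
  IntegerMatrix out(nd, 4);
  double ext[3] = {(g.nx - 1) * spacing[0], (g.ny - 1) * spacing[1],
                   (g.nz - 1) * spacing[2]};
  for (int d = 0; d < nd; ++d) {
    double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
    int lx = -1, ly = -1, lz = -1;
    bool found = false;
    for (double t = 0.0;; t += step) {
      double px = center[0] + t * ux;
      double py = center[1] + t * uy;
      double pz = center[2] + t * uz;
      if (px < -0.5 * spacing[0] || px > ext[0] + 0.5 * spacing[0] ||
          py < -0.5 * spacing[1] || py > ext[1] + 0.5 * spacing[1] ||
          pz < -0.5 * spacing[2] || pz > ext[2] + 0.5 * spacing[2])
        break;
      int xi = (int)std::lround(px / spacing[0]);
      int yi = (int)std::lround(py / spacing[1]);
      int zi = (int)std::lround(pz / spacing[2]);
      if (!g.inside(xi, yi, zi)) continue;
      if (mask[g.idx(xi, yi, zi)]) {
        lx = xi; ly = yi; lz = zi;
        found = true;
      }
    }
    out(d, 0) = lx; out(d, 1) = ly; out(d, 2) = lz;
    out(d, 3) = found ? 1 : 0;
  }
  return out;
}
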