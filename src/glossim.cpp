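#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <queue>
using namespace Rcpp;

// ---- ray casting ----------------------------------------------------------
// Primary-ray intersection of a triangle soup, accelerated by a median-split
// BVH. Geometry is passed as plain matrices so the R side owns the mesh
// representation.

struct Tri { double v0[3], e1[3], e2[3]; int id; };

struct BVHNode {
  double bmin[3], bmax[3];
  int left, right;   // child node indices, -1 for leaf
  int start, count;  // triangle range for leaves
};

struct BVH {
  std::vector<Tri> tris;
  std::vector<int> order;     // triangle indices, permuted by build
  std::vector<double> cent;   // 3 * ntri centroids
  std::vector<BVHNode> nodes;

  void node_bounds(BVHNode &n) {
    for (int k = 0; k < 3; ++k) { n.bmin[k] = 1e300; n.bmax[k] = -1e300; }
    for (int i = n.start; i < n.start + n.count; ++i) {
      const Tri &t = tris[order[i]];
      for (int k = 0; k < 3; ++k) {
        double a = t.v0[k], b = a + t.e1[k], c = a + t.e2[k];
        double lo = std::min(a, std::min(b, c));
        double hi = std::max(a, std::max(b, c));
        if (lo < n.bmin[k]) n.bmin[k] = lo;
        if (hi > n.bmax[k]) n.bmax[k] = hi;
      }
    }
  }

  int build(int start, int count) {
    BVHNode n; n.start = start; n.count = count; n.left = n.right = -1;
    node_bounds(n);
    int idx = (int)nodes.size();
    nodes.push_back(n);
    if (count <= 4) return idx;
    // split along widest centroid axis at the median
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int i = start; i < start + count; ++i)
      for (int k = 0; k < 3; ++k) {
        double c = cent[3 * order[i] + k];
        if (c < lo[k]) lo[k] = c;
        if (c > hi[k]) hi[k] = c;
      }
    int axis = 0; double w = hi[0] - lo[0];
    for (int k = 1; k < 3; ++k) if (hi[k] - lo[k] > w) { w = hi[k] - lo[k]; axis = k; }
    if (w <= 0) return idx;
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int a, int b) { return cent[3 * a + axis] < cent[3 * b + axis]; });
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[idx].left = l; nodes[idx].right = r; nodes[idx].count = 0;
    return idx;
  }
};

static inline bool box_hit(const BVHNode &n, const double o[3], const double inv[3],
                           double tmax) {
  double t0 = 0.0, t1 = tmax;
  for (int k = 0; k < 3; ++k) {
    double ta = (n.bmin[k] - o[k]) * inv[k];
    double tb = (n.bmax[k] - o[k]) * inv[k];
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    if (t0 > t1) return false;
  }
  return true;
}

// Moeller-Trumbore
static inline bool tri_hit(const Tri &tr, const double o[3], const double d[3],
                           double &t, double &u, double &v) {
  double p[3] = { d[1] * tr.e2[2] - d[2] * tr.e2[1],
                  d[2] * tr.e2[0] - d[0] * tr.e2[2],
                  d[0] * tr.e2[1] - d[1] * tr.e2[0] };
  double det = tr.e1[0] * p[0] + tr.e1[1] * p[1] + tr.e1[2] * p[2];
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  double s[3] = { o[0] - tr.v0[0], o[1] - tr.v0[1], o[2] - tr.v0[2] };
  u = (s[0] * p[0] + s[1] * p[1] + s[2] * p[2]) * inv;
  if (u < -1e-9 || u > 1 + 1e-9) return false;
  double q[3] = { s[1] * tr.e1[2] - s[2] * tr.e1[1],
                  s[2] * tr.e1[0] - s[0] * tr.e1[2],
                  s[0] * tr.e1[1] - s[1] * tr.e1[0] };
  v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -1e-9 || u + v > 1 + 1e-9) return false;
  t = (tr.e2[0] * q[0] + tr.e2[1] * q[1] + tr.e2[2] * q[2]) * inv;
  return t > 1e-9;
}

// [[Rcpp::export]]
List cpp_raycast(NumericMatrix vertices, IntegerMatrix faces,
                 NumericMatrix origins, NumericMatrix dirs) {
  int ntri = faces.nrow(), nray = origins.nrow();
  BVH bvh;
  bvh.tris.resize(ntri);
  bvh.order.resize(ntri);
  bvh.cent.resize(3 * ntri);
  for (int i = 0; i < ntri; ++i) {
    int a = faces(i, 0) - 1, b = faces(i, 1) - 1, c = faces(i, 2) - 1;
    Tri &t = bvh.tris[i]; t.id = i;
    for (int k = 0; k < 3; ++k) {
      t.v0[k] = vertices(a, k);
      t.e1[k] = vertices(b, k) - t.v0[k];
      t.e2[k] = vertices(c, k) - t.v0[k];
      bvh.cent[3 * i + k] = (vertices(a, k) + vertices(b, k) + vertices(c, k)) / 3.0;
    }
    bvh.order[i] = i;
  }
  bvh.build(0, ntri);

  IntegerVector hit(nray);
  NumericVector tval(nray), uval(nray), vval(nray);
  std::vector<int> stack(128);
  for (int r = 0; r < nray; ++r) {
    double o[3] = { origins(r, 0), origins(r, 1), origins(r, 2) };
    double d[3] = { dirs(r, 0), dirs(r, 1), dirs(r, 2) };
    double inv[3];
    for (int k = 0; k < 3; ++k)
      inv[k] = (d[k] != 0.0) ? 1.0 / d[k] : 1e300;
    double best = 1e300; int bestid = -1; double bu = 0, bv = 0;
    int sp = 0; stack[sp++] = 0;
    while (sp > 0) {
      const BVHNode &n = bvh.nodes[stack[--sp]];
      if (!box_hit(n, o, inv, best)) continue;
      if (n.left < 0) {
        for (int i = n.start; i < n.start + n.count; ++i) {
          double t, u, v;
          if (tri_hit(bvh.tris[bvh.order[i]], o, d, t, u, v) && t < best) {
            best = t; bestid = bvh.order[i]; bu = u; bv = v;
          }
        }
      } else {
        stack[sp++] = n.left;
        stack[sp++] = n.right;
      }
    }
    hit[r] = bestid + 1;  // 0 = miss, else 1-based face index
    tval[r] = (bestid >= 0) ? best : NA_REAL;
    uval[r] = bu; vval[r] = bv;
  }
  return List::create(_["face"] = hit, _["t"] = tval, _["u"] = uval, _["v"] = vval);
}

// ---- connected components -------------------------------------------------
// BFS labeling of a binary mask under 8-connectivity; label 0 = background.

// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second; q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
      }
    }
  return lab;
}
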