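// Core computational geometry: convex-cell Voronoi tessellation clipped to a
// cube, exact polyhedron moments, and tolerance-based point deduplication.
//
// Each Voronoi cell is obtained by sequentially clipping the bounding cube
// with the perpendicular-bisector half-space of every sufficiently close
// neighbour.  A security-radius bound (a bisector at distance d/2 from the
// generating point cannot cut a cell whose vertices all lie within radius
// d/2) keeps the number of clips per cell nearly constant, so a tessellation
// costs O(G log G) clips rather than O(G^2).

#include <Rcpp.h>
#include <array>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
#include <numeric>
#include <functional>

using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline Vec3 vadd(const Vec3& a, const Vec3& b) {
  return {a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline Vec3 vscale(const Vec3& a, double s) {
  return {a[0] * s, a[1] * s, a[2] * s};
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return {a[1] * b[2] - a[2] * b[1],
          a[2] * b[0] - a[0] * b[2],
          a[0] * b[1] - a[1] * b[0]};
}
static inline double vnorm2(const Vec3& a) { return vdot(a, a); }

struct Poly {
  std::vector<Vec3> V;
  std::vector<std::vector<int> > F;  // ordered vertex loops, outward normals
  std::vector<int> plane;            // -1..-6 cube planes, >=1 neighbour index
};

static Poly make_cube(double L, const Vec3& o) {
  Poly p;
  p.V = {
    {o[0],     o[1],     o[2]},      // 0
    {o[0] + L, o[1],     o[2]},      // 1
    {o[0] + L, o[1] + L, o[2]},      // 2
    {o[0],     o[1] + L, o[2]},      // 3
    {o[0],     o[1],     o[2] + L},  // 4
    {o[0] + L, o[1],     o[2] + L},  // 5
    {o[0] + L, o[1] + L, o[2] + L},  // 6
    {o[0],     o[1] + L, o[2] + L}   // 7
  };
  p.F = {
    {0, 3, 2, 1},  // z = 0, outward -z
    {4, 5, 6, 7},  // z = L, outward +z
    {0, 1, 5, 4},  // y = 0, outward -y
    {3, 7, 6, 2},  // y = L, outward +y
    {0, 4, 7, 3},  // x = 0, outward -x
    {1, 2, 6, 5}   // x = L, outward +x
  };
  p.plane = {-1, -2, -3, -4, -5, -6};
  return p;
}

// Clip poly to the half-space n . x <= d.  Returns true when the polyhedron
// was modified.  eps is the absolute on-plane classification tolerance.
static bool clip_poly(Poly& poly, const Vec3& n, double d, int plane_id,
                      double eps) {
  const int nv = (int)poly.V.size();
  std::vector<double> s(nv);
  bool any_out = false, any_in = false;
  for (int i = 0; i < nv; ++i) {
    s[i] = vdot(n, poly.V[i]) - d;
    if (s[i] > eps) any_out = true;
    else if (s[i] < -eps) any_in = true;
  }
  if (!any_out) return false;
  if (!any_in) {
    poly.V.clear(); poly.F.clear(); poly.plane.clear();
    return true;
  }

  std::vector<Vec3> newV = poly.V;
  std::map<std::pair<int, int>, int> cut_idx;  // shared intersection per edge

  auto cut_point = [&](int a, int b) -> int {
    std::pair<int, int> key(std::min(a, b), std::max(a, b));
    std::map<std::pair<int, int>, int>::iterator it = cut_idx.find(key);
    if (it != cut_idx.end()) return it->second;
    double t = s[a] / (s[a] - s[b]);
    Vec3 p = vadd(poly.V[a], vscale(vsub(poly.V[b], poly.V[a]), t));
    newV.push_back(p);
    int idx = (int)newV.size() - 1;
    cut_idx[key] = idx;
    return idx;
  };

  std::vector<std::vector<int> > newF;
  std::vector<int> newPlane;
  for (size_t f = 0; f < poly.F.size(); ++f) {
    const std::vector<int>& loop = poly.F[f];
    std::vector<int> out;
    const int m = (int)loop.size();
    for (int k = 0; k < m; ++k) {
      int a = loop[k], b = loop[(k + 1) % m];
      bool a_out = s[a] > eps, b_out = s[b] > eps;
      bool a_in = s[a] < -eps, b_in = s[b] < -eps;
      if (!a_out) out.push_back(a);
      if ((a_in && b_out) || (a_out && b_in)) out.push_back(cut_point(a, b));
    }
    // drop consecutive duplicate indices (incl. wrap-around)
    std::vector<int> clean;
    for (size_t k = 0; k < out.size(); ++k)
      if (clean.empty() || clean.back() != out[k]) clean.push_back(out[k]);
    while (clean.size() > 1 && clean.front() == clean.back()) clean.pop_back();
    if ((int)clean.size() >= 3) {
      newF.push_back(clean);
      newPlane.push_back(poly.plane[f]);
    }
  }

  // cut cross-section: every used vertex lying on the clip plane
  std::vector<char> used(newV.size(), 0);
  for (size_t f = 0; f < newF.size(); ++f)
    for (size_t k = 0; k < newF[f].size(); ++k) used[newF[f][k]] = 1;
  std::vector<int> cand;
  for (size_t i = 0; i < newV.size(); ++i) {
    if (!used[i]) continue;
    double si = (i < (size_t)nv) ? s[i] : 0.0;
    if (std::fabs(si) <= eps) cand.push_back((int)i);
  }
  if ((int)cand.size() >= 3) {
    Vec3 c = {0, 0, 0};
    for (size_t k = 0; k < cand.size(); ++k) c = vadd(c, newV[cand[k]]);
    c = vscale(c, 1.0 / (double)cand.size());
    // orthonormal in-plane basis
    Vec3 ref = (std::fabs(n[0]) < 0.9) ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
    Vec3 u = vcross(n, ref);
    u = vscale(u, 1.0 / std::sqrt(vnorm2(u)));
    Vec3 w = vcross(n, u);
    std::vector<std::pair<double, int> > ang;
    for (size_t k = 0; k < cand.size(); ++k) {
      Vec3 r = vsub(newV[cand[k]], c);
      ang.push_back(std::make_pair(std::atan2(vdot(r, w), vdot(r, u)),
                                   cand[k]));
    }
    std::sort(ang.begin(), ang.end());
    std::vector<int> loop;
    for (size_t k = 0; k < ang.size(); ++k)
      if (loop.empty() || loop.back() != ang[k].second)
        loop.push_back(ang[k].second);
    while (loop.size() > 1 && loop.front() == loop.back()) loop.pop_back();
    if ((int)loop.size() >= 3) {
      // orient so the face normal equals +n (outward for the kept side)
      Vec3 e1 = vsub(newV[loop[1]], newV[loop[0]]);
      Vec3 e2 = vsub(newV[loop[2]], newV[loop[0]]);
      if (vdot(vcross(e1, e2), n) < 0) std::reverse(loop.begin(), loop.end());
      newF.push_back(loop);
      newPlane.push_back(plane_id);
    }
  }

  // compact unreferenced vertices
  std::vector<int> remap(newV.size(), -1);
  std::vector<Vec3> finalV;
  for (size_t f = 0; f < newF.size(); ++f)
    for (size_t k = 0; k < newF[f].size(); ++k) {
      int v = newF[f][k];
      if (remap[v] < 0) {
        remap[v] = (int)finalV.size();
        finalV.push_back(newV[v]);
      }
      newF[f][k] = remap[v];
    }
  poly.V.swap(finalV);
  poly.F.swap(newF);
  poly.plane.swap(newPlane);
  return true;
}

// Exact volume, centroid, and second moment about `apex` (which must be
// interior) via tetrahedral fan decomposition of each outward-oriented face.
// For a tetrahedron (apex; a, b, c) with edge vectors u1 = a - apex etc.:
//   vol = det[u1 u2 u3] / 6
//   integral of |x - apex|^2 = vol/10 * (sum_j |u_j|^2 + sum_{j<k} u_j.u_k)
static void poly_moments(const Poly& p, const Vec3& apex, double& vol,
                         Vec3& centroid, double& moment2) {
  vol = 0.0;
  moment2 = 0.0;
  Vec3 csum = {0, 0, 0};
  for (size_t f = 0; f < p.F.size(); ++f) {
    const std::vector<int>& loop = p.F[f];
    for (size_t k = 1; k + 1 < loop.size(); ++k) {
      Vec3 u1 = vsub(p.V[loop[0]], apex);
      Vec3 u2 = vsub(p.V[loop[k]], apex);
      Vec3 u3 = vsub(p.V[loop[k + 1]], apex);
      double v = vdot(u1, vcross(u2, u3)) / 6.0;
      vol += v;
      Vec3 tc = vscale(vadd(vadd(u1, u2), u3), 0.25);  // rel. to apex
      csum = vadd(csum, vscale(tc, v));
      double q = vnorm2(u1) + vnorm2(u2) + vnorm2(u3) +
                 vdot(u1, u2) + vdot(u1, u3) + vdot(u2, u3);
      moment2 += v * q / 10.0;
    }
  }
  centroid = vadd(apex, vscale(csum, 1.0 / vol));
}

static List poly_to_list(const Poly& p, double vol, const Vec3& cen,
                         double m2) {
  NumericMatrix verts((int)p.V.size(), 3);
  for (size_t i = 0; i < p.V.size(); ++i) {
    verts(i, 0) = p.V[i][0];
    verts(i, 1) = p.V[i][1];
    verts(i, 2) = p.V[i][2];
  }
  List faces((int)p.F.size());
  IntegerVector plane((int)p.F.size());
  for (size_t f = 0; f < p.F.size(); ++f) {
    IntegerVector loop((int)p.F[f].size());
    for (size_t k = 0; k < p.F[f].size(); ++k) loop[k] = p.F[f][k] + 1;
    faces[f] = loop;
    plane[f] = p.plane[f];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces,
                      _["plane"] = plane, _["volume"] = vol,
                      _["centroid"] = NumericVector::create(cen[0], cen[1],
                                                            cen[2]),
                      _["second_moment"] = m2);
}

// [[Rcpp::export]]
List cpp_bounded_voronoi(NumericMatrix pts, double L, NumericVector origin) {
  const int G = pts.nrow();
  Vec3 o = {origin[0], origin[1], origin[2]};
  const double eps = 1e-10 * L;
  List cells(G);

  std::vector<Vec3> P(G);
  for (int i = 0; i < G; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};

  std::vector<int> order(std::max(G - 1, 0));
  std::vector<double> dist2(G);

  for (int i = 0; i < G; ++i) {
    Poly cell = make_cube(L, o);
    // neighbours sorted by distance; security radius prunes far bisectors
    int m = 0;
    for (int j = 0; j < G; ++j)
      if (j != i) { order[m++] = j; dist2[j] = vnorm2(vsub(P[j], P[i])); }
    std::sort(order.begin(), order.begin() + m,
              [&](int a, int b) { return dist2[a] < dist2[b]; });

    double rmax2 = 0.0;
    for (size_t k = 0; k < cell.V.size(); ++k)
      rmax2 = std::max(rmax2, vnorm2(vsub(cell.V[k], P[i])));

    for (int k = 0; k < m; ++k) {
      int j = order[k];
      if (dist2[j] > 4.0 * rmax2) break;
      Vec3 diff = vsub(P[j], P[i]);
      double len = std::sqrt(vnorm2(diff));
      Vec3 n = vscale(diff, 1.0 / len);
      Vec3 mid = vscale(vadd(P[i], P[j]), 0.5);
      double d = vdot(n, mid);
      if (clip_poly(cell, n, d, j + 1, eps)) {
        if (cell.V.empty())
          stop("cell %d vanished during clipping (degenerate input)", i + 1);
        rmax2 = 0.0;
        for (size_t q = 0; q < cell.V.size(); ++q)
          rmax2 = std::max(rmax2, vnorm2(vsub(cell.V[q], P[i])));
      }
    }
    double vol, m2;
    Vec3 cen;
    poly_moments(cell, P[i], vol, cen, m2);
    cells[i] = poly_to_list(cell, vol, cen, m2);
  }
  return cells;
}

// [[Rcpp::export]]
List cpp_poly_props(NumericMatrix verts, List faces, NumericVector about) {
  Poly p;
  p.V.resize(verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i)
    p.V[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};
  for (int f = 0; f < faces.size(); ++f) {
    IntegerVector loop = faces[f];
    std::vector<int> l(loop.size());
    for (int k = 0; k < loop.size(); ++k) l[k] = loop[k] - 1;
    p.F.push_back(l);
    p.plane.push_back(0);
  }
  // apex at the vertex mean (interior for convex polyhedra); faces may be
  // oriented either way, so take absolute tetra volumes
  Vec3 apex = {0, 0, 0};
  for (size_t i = 0; i < p.V.size(); ++i) apex = vadd(apex, p.V[i]);
  apex = vscale(apex, 1.0 / (double)p.V.size());

  double vol = 0.0, m2 = 0.0;
  Vec3 csum = {0, 0, 0};
  for (size_t f = 0; f < p.F.size(); ++f) {
    const std::vector<int>& loop = p.F[f];
    for (size_t k = 1; k + 1 < loop.size(); ++k) {
      Vec3 u1 = vsub(p.V[loop[0]], apex);
      Vec3 u2 = vsub(p.V[loop[k]], apex);
      Vec3 u3 = vsub(p.V[loop[k + 1]], apex);
      double v = std::fabs(vdot(u1, vcross(u2, u3))) / 6.0;
      vol += v;
      Vec3 tc = vscale(vadd(vadd(u1, u2), u3), 0.25);
      csum = vadd(csum, vscale(tc, v));
      double q = vnorm2(u1) + vnorm2(u2) + vnorm2(u3) +
                 vdot(u1, u2) + vdot(u1, u3) + vdot(u2, u3);
      m2 += v * q / 10.0;
    }
  }
  if (vol <= 0) stop("degenerate polyhedron: non-positive volume");
  Vec3 cen = vadd(apex, vscale(csum, 1.0 / vol));
  // parallel-axis shift of the second moment from apex to `about`
  Vec3 a2q = vsub(apex, {about[0], about[1], about[2]});
  Vec3 c2a = vsub(cen, apex);
  double m2q = m2 + 2.0 * vol * vdot(a2q, c2a) + vol * vnorm2(a2q);
  return List::create(_["volume"] = vol,
                      _["centroid"] = NumericVector::create(cen[0], cen[1],
                                                            cen[2]),
                      _["second_moment"] = m2q);
}

// Tolerance-based point merging: single-linkage union of all pairs within
// euclidean distance tol, found by a sweep over x-sorted points.  Returns
// 1-based cluster ids numbered by first appearance.
// [[Rcpp::export]]
IntegerVector cpp_dedup_points(NumericMatrix pts, double tol) {
  const int n = pts.nrow();
  std::vector<int> parent(n);
  std::iota(parent.begin(), parent.end(), 0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return pts(a, 0) < pts(b, 0); });
  const double tol2 = tol * tol;
  for (int a = 0; a < n; ++a) {
    int i = idx[a];
    for (int b = a + 1; b < n; ++b) {
      int j = idx[b];
      if (pts(j, 0) - pts(i, 0) > tol) break;
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      if (dx * dx + dy * dy + dz * dz <= tol2) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
      }
    }
  }
  IntegerVector out(n);
  std::map<int, int> label;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    std::map<int, int>::iterator it = label.find(r);
    if (it == label.end()) { label[r] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}
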