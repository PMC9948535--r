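// KMT reduction of a closed polygon: repeatedly delete a vertex whose
// spanned triangle is intersected by no other edge of the polygon. The
// operation is a sequence of elementary deformations, so the knot type of
// the cycle is preserved while the vertex count shrinks drastically.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 sub(const V3 &a, const V3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline V3 add(const V3 &a, const V3 &b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
inline V3 scl(double s, const V3 &a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot3(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline V3 crs(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
inline double nrm(const V3 &a) { return std::sqrt(dot3(a, a)); }

// 2D helpers for the coplanar branch
inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

bool point_in_tri2(double px, double py, const double tx[3],
                   const double ty[3], double eps) {
  double d1 = cross2(tx[1] - tx[0], ty[1] - ty[0], px - tx[0], py - ty[0]);
  double d2 = cross2(tx[2] - tx[1], ty[2] - ty[1], px - tx[1], py - ty[1]);
  double d3 = cross2(tx[0] - tx[2], ty[0] - ty[2], px - tx[2], py - ty[2]);
  bool has_neg = (d1 < -eps) || (d2 < -eps) || (d3 < -eps);
  bool has_pos = (d1 > eps) || (d2 > eps) || (d3 > eps);
  return !(has_neg && has_pos);
}

bool seg2_intersect(double p0x, double p0y, double p1x, double p1y,
                    double q0x, double q0y, double q1x, double q1y,
                    double eps) {
  double rx = p1x - p0x, ry = p1y - p0y;
  double sx = q1x - q0x, sy = q1y - q0y;
  double denom = cross2(rx, ry, sx, sy);
  double qpx = q0x - p0x, qpy = q0y - p0y;
  if (std::fabs(denom) <= eps) {
    // parallel: overlapping collinear counts as contact
    if (std::fabs(cross2(qpx, qpy, rx, ry)) > eps) return false;
    double rr = rx * rx + ry * ry;
    if (rr <= eps) return false;
    double t0 = (qpx * rx + qpy * ry) / rr;
    double t1 = t0 + (sx * rx + sy * ry) / rr;
    if (t0 > t1) std::swap(t0, t1);
    return (t1 >= -eps) && (t0 <= 1.0 + eps);
  }
  double t = cross2(qpx, qpy, sx, sy) / denom;
  double s = cross2(qpx, qpy, rx, ry) / denom;
  return t >= -eps && t <= 1.0 + eps && s >= -eps && s <= 1.0 + eps;
}

// does segment q0-q1 touch triangle a,b,c?
bool seg_hits_triangle(const V3 &q0, const V3 &q1, const V3 &a, const V3 &b,
                       const V3 &c, double tol) {
  V3 ab = sub(b, a), ac = sub(c, a);
  V3 n = crs(ab, ac);
  double area2 = nrm(n);
  if (area2 <= tol * tol) return false; // degenerate triangle: no barrier
  V3 dirv = sub(q1, q0);
  double denom = dot3(n, dirv);
  double dist0 = dot3(n, sub(q0, a));
  double scale = area2;
  if (std::fabs(denom) <= tol * scale) {
    // segment parallel to the triangle plane
    if (std::fabs(dist0) > tol * scale) return false; // clearly off-plane
    // coplanar: work in 2D coordinates of the plane
    V3 e1 = scl(1.0 / nrm(ab), ab);
    V3 e2 = crs(scl(1.0 / area2, n), e1);
    double tx[3], ty[3];
    const V3 *tv[3] = {&a, &b, &c};
    for (int k = 0; k < 3; ++k) {
      V3 w = sub(*tv[k], a);
      tx[k] = dot3(w, e1);
      ty[k] = dot3(w, e2);
    }
    V3 w0 = sub(q0, a), w1 = sub(q1, a);
    double p0x = dot3(w0, e1), p0y = dot3(w0, e2);
    double p1x = dot3(w1, e1), p1y = dot3(w1, e2);
    double eps = 1e-12;
    if (point_in_tri2(p0x, p0y, tx, ty, eps)) return true;
    if (point_in_tri2(p1x, p1y, tx, ty, eps)) return true;
    for (int k = 0; k < 3; ++k) {
      int k2 = (k + 1) % 3;
      if (seg2_intersect(p0x, p0y, p1x, p1y, tx[k], ty[k], tx[k2], ty[k2],
                         eps))
        return true;
    }
    return false;
  }
  double t = -dist0 / denom;
  if (t < -tol || t > 1.0 + tol) return false;
  V3 p = add(q0, scl(t, dirv));
  // barycentric test
  V3 ap = sub(p, a);
  double d00 = dot3(ab, ab), d01 = dot3(ab, ac), d11 = dot3(ac, ac);
  double d20 = dot3(ap, ab), d21 = dot3(ap, ac);
  double den = d00 * d11 - d01 * d01;
  if (den <= 0.0) return false;
  double v = (d11 * d20 - d01 * d21) / den;
  double w = (d00 * d21 - d01 * d20) / den;
  double eps = 1e-12;
  return v >= -eps && w >= -eps && (v + w) <= 1.0 + eps;
}

} // namespace

// [[Rcpp::export(name = "cpp_kmt_reduce")]]
NumericMatrix cpp_kmt_reduce(NumericMatrix verts, double tol) {
  int n0 = verts.nrow();
  std::vector<V3> v(n0);
  for (int i = 0; i < n0; ++i) v[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};

  bool changed = true;
  const double shrink = 1e-6;
  while (changed && (int)v.size() > 3) {
    changed = false;
    int n = (int)v.size();
    for (int k = 0; k < n && n > 3; ++k) {
      int ip = (k + n - 1) % n, in = (k + 1) % n;
      const V3 &A = v[ip], &B = v[k], &C = v[in];
      V3 nvec = crs(sub(B, A), sub(C, A));
      bool deletable;
      if (nrm(nvec) <= tol) {
        // degenerate triangle: deletion is safe only if B lies between A
        // and C on the segment (no spike is removed)
        V3 acv = sub(C, A);
        double L2 = dot3(acv, acv);
        double t = L2 > 0 ? dot3(sub(B, A), acv) / L2 : -1.0;
        deletable = (t >= -tol && t <= 1.0 + tol);
      } else {
        deletable = true;
        for (int e = 0; e < n && deletable; ++e) {
          int e2 = (e + 1) % n;
          if (e == k || e2 == k) continue; // the two triangle edges
          V3 q0 = v[e], q1 = v[e2];
          // shrink edges that share a vertex with the triangle corners
          if (e == ip || e == in) q0 = add(q0, scl(shrink, sub(q1, q0)));
          if (e2 == ip || e2 == in) q1 = add(q1, scl(shrink, sub(q0, q1)));
          if (seg_hits_triangle(q0, q1, A, B, C, tol)) deletable = false;
        }
      }
      if (deletable) {
        v.erase(v.begin() + k);
        --n;
        --k;
        changed = true;
      }
    }
  }

  NumericMatrix out((int)v.size(), 3);
  for (int i = 0; i < (int)v.size(); ++i) {
    out(i, 0) = v[i].x;
    out(i, 1) = v[i].y;
    out(i, 2) = v[i].z;
  }
  return out;
}
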