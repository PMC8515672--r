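// Mesh proximity primitives: exact closest point-to-triangle queries
// accelerated by a uniform grid over triangle bounding boxes (the grid only
// prunes candidates), plus surface-crossing tests and a batched per-frame
// clearance series for posed meshes.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}

// closest point on triangle (a,b,c) to p  [Ericson, Real-Time Collision
// Detection, 5.1.5]
static Vec3 closestPointTriangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                 const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return a + ab * (d1 / (d1 - d3));
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return a + ac * (d2 / (d2 - d6));
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  return a + ab * (vb * denom) + ac * (vc * denom);
}

struct TriGrid {
  std::vector<Vec3> V;
  std::vector<int> F;  // 3 per face, 0-based
  Vec3 lo, hi;
  double cell;
  int nx, ny, nz;
  std::vector<std::vector<int> > bins;
  mutable std::vector<int> stamp;
  mutable int stampv;

  TriGrid(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
    int nv = Vm.nrow(), nf = Fm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    F.resize(3 * nf);
    for (int f = 0; f < nf; ++f)
      for (int k = 0; k < 3; ++k) F[3 * f + k] = Fm(f, k) - 1;
    lo = Vec3(R_PosInf, R_PosInf, R_PosInf);
    hi = Vec3(R_NegInf, R_NegInf, R_NegInf);
    for (int i = 0; i < nv; ++i) {
      lo.x = std::min(lo.x, V[i].x); hi.x = std::max(hi.x, V[i].x);
      lo.y = std::min(lo.y, V[i].y); hi.y = std::max(hi.y, V[i].y);
      lo.z = std::min(lo.z, V[i].z); hi.z = std::max(hi.z, V[i].z);
    }
    double ext = std::max(hi.x - lo.x, std::max(hi.y - lo.y, hi.z - lo.z));
    if (ext <= 0) ext = 1.0;
    int n = (int)std::min(24.0, std::max(4.0, std::cbrt((double)std::max(nf, 1))));
    cell = ext / n;
    nx = (int)((hi.x - lo.x) / cell) + 1;
    ny = (int)((hi.y - lo.y) / cell) + 1;
    nz = (int)((hi.z - lo.z) / cell) + 1;
    bins.resize((size_t)nx * ny * nz);
    for (int f = 0; f < nf; ++f) {
      Vec3 tlo(R_PosInf, R_PosInf, R_PosInf), thi(R_NegInf, R_NegInf, R_NegInf);
      for (int k = 0; k < 3; ++k) {
        const Vec3& v = V[F[3 * f + k]];
        tlo.x = std::min(tlo.x, v.x); thi.x = std::max(thi.x, v.x);
        tlo.y = std::min(tlo.y, v.y); thi.y = std::max(thi.y, v.y);
        tlo.z = std::min(tlo.z, v.z); thi.z = std::max(thi.z, v.z);
      }
      int i0 = ci(tlo.x, lo.x, nx), i1 = ci(thi.x, lo.x, nx);
      int j0 = ci(tlo.y, lo.y, ny), j1 = ci(thi.y, lo.y, ny);
      int k0 = ci(tlo.z, lo.z, nz), k1 = ci(thi.z, lo.z, nz);
      for (int i = i0; i <= i1; ++i)
        for (int j = j0; j <= j1; ++j)
          for (int k = k0; k <= k1; ++k)
            bins[idx(i, j, k)].push_back(f);
    }
    stamp.assign(nf, -1);
    stampv = 0;
  }
  int ci(double v, double origin, int n) const {
    int i = (int)std::floor((v - origin) / cell);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }
  size_t idx(int i, int j, int k) const { return ((size_t)i * ny + j) * nz + k; }
  Vec3 tri(int f, int k) const { return V[F[3 * f + k]]; }

  // squared distance from p to the mesh bounding box
  double bbox_d2(const Vec3& p) const {
    double dx = std::max(0.0, std::max(lo.x - p.x, p.x - hi.x));
    double dy = std::max(0.0, std::max(lo.y - p.y, p.y - hi.y));
    double dz = std::max(0.0, std::max(lo.z - p.z, p.z - hi.z));
    return dx * dx + dy * dy + dz * dz;
  }

  // closest point on the mesh to p, searching only while the result could be
  // closer than sqrt(bound2); returns squared distance (inf if pruned out)
  double closest(const Vec3& p, Vec3& cp, int& fidx, double bound2) const {
    if (bbox_d2(p) > bound2) return R_PosInf;
    ++stampv;
    double best = bound2;
    bool found = false;
    int pi = ci(p.x, lo.x, nx), pj = ci(p.y, lo.y, ny), pk = ci(p.z, lo.z, nz);
    int maxring = nx + ny + nz;
    for (int ring = 0; ring <= maxring; ++ring) {
      if (ring >= 2) {
        double lb = (ring - 1) * cell;
        if (lb * lb > best) break;
      }
      int i0 = pi - ring, i1 = pi + ring;
      int j0 = pj - ring, j1 = pj + ring;
      int k0 = pk - ring, k1 = pk + ring;
      for (int i = std::max(0, i0); i <= std::min(nx - 1, i1); ++i) {
        bool iface = (i == i0 || i == i1);
        for (int j = std::max(0, j0); j <= std::min(ny - 1, j1); ++j) {
          bool jface = (j == j0 || j == j1);
          for (int k = std::max(0, k0); k <= std::min(nz - 1, k1); ++k) {
            bool shell = iface || jface || (k == k0 || k == k1);
            if (!shell) continue;
            const std::vector<int>& b = bins[idx(i, j, k)];
            for (size_t t = 0; t < b.size(); ++t) {
              int f = b[t];
              if (stamp[f] == stampv) continue;
              stamp[f] = stampv;
              Vec3 q = closestPointTriangle(p, tri(f, 0), tri(f, 1), tri(f, 2));
              Vec3 d = p - q;
              double d2 = dot(d, d);
              if (d2 < best) { best = d2; cp = q; fidx = f; found = true; }
            }
          }
        }
      }
    }
    return found ? best : R_PosInf;
  }
};

// [[Rcpp::export]]
List cpp_points_mesh_closest(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriGrid g(V, F);
  int n = P.nrow();
  NumericVector d(n);
  NumericMatrix cp(n, 3);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2)), q;
    int f = -1;
    double d2 = g.closest(p, q, f, R_PosInf);
    d[i] = std::sqrt(d2);
    cp(i, 0) = q.x; cp(i, 1) = q.y; cp(i, 2) = q.z;
    face[i] = f + 1;
  }
  return List::create(_["dist"] = d, _["closest"] = cp, _["face"] = face);
}

// segment-triangle intersection (Moller-Trumbore restricted to the segment)
static bool segTri(const Vec3& p, const Vec3& q, const Vec3& a, const Vec3& b,
                   const Vec3& c) {
  Vec3 dir = q - p;
  Vec3 e1 = b - a, e2 = c - a;
  Vec3 h = cross(dir, e2);
  double det = dot(e1, h);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  Vec3 s = p - a;
  double u = dot(s, h) * inv;
  if (u < 0 || u > 1) return false;
  Vec3 qv = cross(s, e1);
  double v = dot(dir, qv) * inv;
  if (v < 0 || u + v > 1) return false;
  double t = dot(e2, qv) * inv;
  return t >= 0 && t <= 1;
}

static bool meshesCross(const TriGrid& ga, const TriGrid& gb) {
  int nfa = (int)ga.F.size() / 3;
  for (int f = 0; f < nfa; ++f) {
    Vec3 t[3] = { ga.tri(f, 0), ga.tri(f, 1), ga.tri(f, 2) };
    Vec3 tlo(R_PosInf, R_PosInf, R_PosInf), thi(R_NegInf, R_NegInf, R_NegInf);
    for (int k = 0; k < 3; ++k) {
      tlo.x = std::min(tlo.x, t[k].x); thi.x = std::max(thi.x, t[k].x);
      tlo.y = std::min(tlo.y, t[k].y); thi.y = std::max(thi.y, t[k].y);
      tlo.z = std::min(tlo.z, t[k].z); thi.z = std::max(thi.z, t[k].z);
    }
    if (thi.x < gb.lo.x || tlo.x > gb.hi.x || thi.y < gb.lo.y ||
        tlo.y > gb.hi.y || thi.z < gb.lo.z || tlo.z > gb.hi.z) continue;
    int i0 = gb.ci(tlo.x, gb.lo.x, gb.nx), i1 = gb.ci(thi.x, gb.lo.x, gb.nx);
    int j0 = gb.ci(tlo.y, gb.lo.y, gb.ny), j1 = gb.ci(thi.y, gb.lo.y, gb.ny);
    int k0 = gb.ci(tlo.z, gb.lo.z, gb.nz), k1 = gb.ci(thi.z, gb.lo.z, gb.nz);
    ++gb.stampv;
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k) {
          const std::vector<int>& bin = gb.bins[gb.idx(i, j, k)];
          for (size_t u = 0; u < bin.size(); ++u) {
            int fb = bin[u];
            if (gb.stamp[fb] == gb.stampv) continue;
            gb.stamp[fb] = gb.stampv;
            Vec3 s[3] = { gb.tri(fb, 0), gb.tri(fb, 1), gb.tri(fb, 2) };
            for (int e = 0; e < 3; ++e) {
              if (segTri(t[e], t[(e + 1) % 3], s[0], s[1], s[2])) return true;
              if (segTri(s[e], s[(e + 1) % 3], t[0], t[1], t[2])) return true;
            }
          }
        }
  }
  return false;
}

// [[Rcpp::export]]
bool cpp_meshes_cross(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
                      IntegerMatrix FB) {
  TriGrid ga(VA, FA), gb(VB, FB);
  return meshesCross(ga, gb);
}

// symmetric minimum vertex-to-surface distance between two static meshes
// [[Rcpp::export]]
List cpp_mesh_clearance(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
                        IntegerMatrix FB) {
  TriGrid gb(VB, FB), ga(VA, FA);
  double best = R_PosInf;
  Vec3 pa, pb;
  for (size_t i = 0; i < ga.V.size(); ++i) {
    Vec3 q;
    int f;
    double d2 = gb.closest(ga.V[i], q, f, best);
    if (d2 < best) { best = d2; pa = ga.V[i]; pb = q; }
  }
  for (size_t i = 0; i < gb.V.size(); ++i) {
    Vec3 q;
    int f;
    double d2 = ga.closest(gb.V[i], q, f, best);
    if (d2 < best) { best = d2; pa = q; pb = gb.V[i]; }
  }
  bool crossing = meshesCross(ga, gb);
  return List::create(
    _["dist"] = crossing ? 0.0 : std::sqrt(best),
    _["crossing"] = crossing,
    _["point_a"] = NumericVector::create(pa.x, pa.y, pa.z),
    _["point_b"] = NumericVector::create(pb.x, pb.y, pb.z));
}

// Per-frame clearance between mesh A posed by (R_i, t_i) and static mesh B,
// both grids built once. Frames flagged invalid yield NA.
// [[Rcpp::export]]
List cpp_contact_series(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
                        IntegerMatrix FB, NumericVector rotations,
                        NumericMatrix translations, LogicalVector valid,
                        double cross_check_below) {
  TriGrid ga(VA, FA), gb(VB, FB);
  IntegerVector dim = rotations.attr("dim");
  int n = dim[2];
  NumericVector dist(n, NA_REAL);
  LogicalVector crossing(n, NA_LOGICAL);
  NumericMatrix pA(n, 3), pB(n, 3);
  int seedA = 0, seedB = 0;
  int nva = VA.nrow(), nvb = VB.nrow();
  std::vector<Vec3> Aw(nva), Bl(nvb);
  for (int fr = 0; fr < n; ++fr) {
    if (!valid[fr]) continue;
    double R[9];
    for (int k = 0; k < 9; ++k) R[k] = rotations[fr * 9 + k];  // column-major
    Vec3 t(translations(fr, 0), translations(fr, 1), translations(fr, 2));
    for (int i = 0; i < nva; ++i) {
      const Vec3& v = ga.V[i];
      Aw[i] = Vec3(R[0] * v.x + R[3] * v.y + R[6] * v.z + t.x,
                   R[1] * v.x + R[4] * v.y + R[7] * v.z + t.y,
                   R[2] * v.x + R[5] * v.y + R[8] * v.z + t.z);
    }
    for (int i = 0; i < nvb; ++i) {
      Vec3 u = gb.V[i] - t;  // inverse pose: R' * (u - t)
      Bl[i] = Vec3(R[0] * u.x + R[1] * u.y + R[2] * u.z,
                   R[3] * u.x + R[4] * u.y + R[5] * u.z,
                   R[6] * u.x + R[7] * u.y + R[8] * u.z);
    }
    double best = R_PosInf;
    Vec3 bpa, bpb, q;
    int f;
    bool fromA = true;
    int bi = seedA;
    // seed with last frame's closest vertices, then sweep everything bounded
    double d2 = gb.closest(Aw[seedA], q, f, best);
    if (d2 < best) { best = d2; bpa = Aw[seedA]; bpb = q; }
    d2 = ga.closest(Bl[seedB], q, f, best);
    if (d2 < best) {
      best = d2;
      bpa = q; bpb = Bl[seedB];
      fromA = false; bi = seedB;
    }
    for (int i = 0; i < nva; ++i) {
      d2 = gb.closest(Aw[i], q, f, best);
      if (d2 < best) { best = d2; bpa = Aw[i]; bpb = q; fromA = true; bi = i; }
    }
    for (int i = 0; i < nvb; ++i) {
      d2 = ga.closest(Bl[i], q, f, best);
      if (d2 < best) { best = d2; bpa = q; bpb = Bl[i]; fromA = false; bi = i; }
    }
    if (fromA) {
      seedA = bi;
      // bpb is in B/world frame already; bpa too
      pA(fr, 0) = bpa.x; pA(fr, 1) = bpa.y; pA(fr, 2) = bpa.z;
      pB(fr, 0) = bpb.x; pB(fr, 1) = bpb.y; pB(fr, 2) = bpb.z;
    } else {
      seedB = bi;
      // both points are in A's local frame; map back to world
      Vec3 wa(R[0] * bpa.x + R[3] * bpa.y + R[6] * bpa.z + t.x,
              R[1] * bpa.x + R[4] * bpa.y + R[7] * bpa.z + t.y,
              R[2] * bpa.x + R[5] * bpa.y + R[8] * bpa.z + t.z);
      Vec3 wb(R[0] * bpb.x + R[3] * bpb.y + R[6] * bpb.z + t.x,
              R[1] * bpb.x + R[4] * bpb.y + R[7] * bpb.z + t.y,
              R[2] * bpb.x + R[7] * bpb.y + R[8] * bpb.z + t.z);
      pA(fr, 0) = wa.x; pA(fr, 1) = wa.y; pA(fr, 2) = wa.z;
      pB(fr, 0) = wb.x; pB(fr, 1) = wb.y; pB(fr, 2) = wb.z;
    }
    double d = std::sqrt(best);
    bool cr = false;
    if (d <= cross_check_below) {
      NumericMatrix VAw(nva, 3);
      for (int i = 0; i < nva; ++i) {
        VAw(i, 0) = Aw[i].x; VAw(i, 1) = Aw[i].y; VAw(i, 2) = Aw[i].z;
      }
      TriGrid gaw(VAw, FA);
      cr = meshesCross(gaw, gb);
    }
    crossing[fr] = cr;
    dist[fr] = cr ? 0.0 : d;
  }
  return List::create(_["dist"] = dist, _["crossing"] = crossing,
                      _["point_a"] = pA, _["point_b"] = pB);
}
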