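#include "hemesh.h"
#include <queue>
using namespace Rcpp;

// Exact polyhedral geodesics: single-source-all-vertices distances by
// continuous-Dijkstra propagation of distance windows across unfolded
// triangles, with vertex-oriented pruning against the current per-vertex
// distance bounds. Distances only; no path reconstruction.
//
// A window lives on a halfedge h and describes a family of unfolded straight
// paths entering face(h) through the interval [b0, b1] of h (b measured from
// from(h)). The pseudo-source sits at planar distance d0 / d1 from the two
// interval endpoints, on the side opposite to face(h), and carries an
// accumulated surface distance sigma from the true source.
//
// Numerical tolerances are relative to the local edge length (1e-12).

namespace {

struct Event {
  double key;
  int kind;     // 0 = window, 1 = pseudo-source vertex
  int id;       // halfedge (window) or vertex (pseudo-source)
  double b0, b1, d0, d1, sigma;
};
struct EventCmp {
  bool operator()(const Event& a, const Event& b) const { return a.key > b.key; }
};

constexpr double EPSW = 1e-12;      // relative interval/coincidence tolerance
constexpr double EPSV = 1e-7;       // vertex-capture tolerance (see below)
// Angle-sum excess above which a vertex acts as a saddle pseudo-source.
// Shortest paths can bend only around vertices with angle excess, inside
// the "shadow" cone of width = excess directly behind the incoming
// direction; saddle windows are emitted clipped to that cone (padded by
// SHADOW_PAD to absorb bookkeeping rounding), which keeps smooth curved
// meshes -- where a large fraction of vertices carry noise-level excess --
// from flooding the queue with near-duplicate full-ring windows.
constexpr double SADDLE_TOL = 1e-9;
constexpr double SHADOW_PAD = 0.002;  // rad, each side of the shadow cone

// EPSV widens only the test of whether a window's wedge reaches a vertex:
// on structured meshes many geodesics pass exactly through mesh vertices,
// and after repeated window splitting the bounding rays carry ~1e-10
// relative rounding error, so an exact-tolerance test can leave such
// vertices uncovered. The injected distance is always computed exactly from
// the unfolded pseudo-source, so a capture that is off by an angle eps can
// perturb the distance only at O(eps^2), far below the pruning margin.

// How a vertex obtained its current distance; used to orient the shadow
// cone when the vertex later acts as a saddle pseudo-source.
struct Prov {
  int role;  // -1 none, 0 apex of window h, 1 from(h), 2 to(h), 3 along spoke h
  int h;
  double px, py;  // window pseudo-source in h's frame (roles 0-2)
};

class GeoSolver {
 public:
  explicit GeoSolver(const HEMesh& M) : M(M) {
    dist.assign(M.nv, inf());
    pseudo.assign(M.nv, 0);
    propagated_at.assign(M.nv, inf());
    prov.assign(M.nv, Prov{-1, -1, 0, 0});
    for (int v = 0; v < M.nv; ++v)
      pseudo[v] = (M.vbnd[v] || M.angsum[v] > 2 * M_PI + SADDLE_TOL) ? 1 : 0;
    // spoke fan tables: cumulative angle of each outgoing halfedge around
    // its origin vertex (interior vertices only), plus per-corner angles
    int nh = 3 * M.nf;
    hang.resize(nh);
    for (int h = 0; h < nh; ++h) {
      double a = M.elen[h], b = M.elen[M.prv(h)], c = M.elen[M.nxt(h)];
      double ca = (a * a + b * b - c * c) / (2 * a * b);
      hang[h] = std::acos(std::max(-1.0, std::min(1.0, ca)));
    }
    he_theta.assign(nh, 0.0);
    for (int v = 0; v < M.nv; ++v) {
      if (M.vbnd[v] || M.vout[v].empty()) continue;
      int h0 = M.vout[v][0], h = h0;
      double th = 0;
      do {
        he_theta[h] = th;
        th += hang[h];
        h = M.twin[M.prv(h)];
      } while (h >= 0 && h != h0);
    }
  }

  static double inf() { return std::numeric_limits<double>::infinity(); }

  // Solve from `src`, writing distances into `out` (length nv).
  void run(int src, double* out) {
    std::fill(dist.begin(), dist.end(), inf());
    std::fill(propagated_at.begin(), propagated_at.end(), inf());
    std::fill(prov.begin(), prov.end(), Prov{-1, -1, 0, 0});
    q = std::priority_queue<Event, std::vector<Event>, EventCmp>();
    srcv = src;
    dist[src] = 0.0;
    propagate_vertex(src);
    long long guard = 0;
    const long long guard_max = 2e9;
    while (!q.empty()) {
      if (++guard > guard_max) stop("geodesic propagation failed to converge");
      Event e = q.top();
      q.pop();
      if (e.kind == 1) {
        int v = e.id;
        if (e.sigma > dist[v] * (1 + EPSW)) continue;            // stale
        if (propagated_at[v] <= dist[v] * (1 + EPSW)) continue;  // already done
        propagate_vertex(v);
      } else {
        if (!dominated(e.id, e.b0, e.b1, e.d0, e.d1, e.sigma))
          propagate_window(e);
      }
    }
    for (int v = 0; v < M.nv; ++v) out[v] = dist[v];
  }

 private:
  const HEMesh& M;
  std::vector<double> dist;
  std::vector<char> pseudo;
  std::vector<double> propagated_at;
  std::vector<Prov> prov;
  std::vector<double> hang;      // corner angle at from(h) in face(h)
  std::vector<double> he_theta;  // cumulative fan angle of spoke h at from(h)
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;
  int srcv = -1;

  void try_update(int v, double val, const Prov& p) {
    if (val < dist[v] * (1 - 1e-15) || (dist[v] == inf() && val < inf())) {
      dist[v] = val;
      prov[v] = p;
      if (pseudo[v]) q.push(Event{val, 1, v, 0, 0, 0, 0, val});
    }
  }

  static double ang_between(double ax, double ay, double bx, double by) {
    double d = (ax * bx + ay * by) /
               std::max(1e-300, std::hypot(ax, ay) * std::hypot(bx, by));
    return std::acos(std::max(-1.0, std::min(1.0, d)));
  }

  // Fan coordinate (at vertex v) of the direction back toward the path that
  // set dist[v].
  double psi_from_prov(const Prov& p) const {
    switch (p.role) {
      case 3:
        return he_theta[p.h];
      case 0: {  // v is the apex of window halfedge h
        int h = p.h;
        double L = M.elen[h], cA = M.elen[M.prv(h)], cB = M.elen[M.nxt(h)];
        double cx = (L * L + cA * cA - cB * cB) / (2 * L);
        double cy = std::sqrt(std::max(0.0, cA * cA - cx * cx));
        double beta = ang_between(-cx, -cy, p.px - cx, p.py - cy);
        beta = std::min(beta, hang[M.prv(h)]);
        return he_theta[M.prv(h)] + beta;
      }
      case 1:  // v = from(h): pseudo-source side is fan-decreasing from h
        return he_theta[p.h] - ang_between(1, 0, p.px, p.py);
      case 2: {  // v = to(h): fan-increasing from the spoke twin(h)
        double L = M.elen[p.h];
        int s = M.twin[p.h];
        return he_theta[s] + ang_between(-1, 0, p.px - L, p.py);
      }
      default:
        return 0;  // unreachable; full emission is used instead
    }
  }

  // Emit windows from a (pseudo-)source vertex v and relax its one-ring.
  // The true source, boundary vertices, and vertices without direction
  // provenance broadcast into every incident face; saddle vertices emit
  // only into the shadow cone behind their incoming direction.
  void propagate_vertex(int v) {
    double dv = dist[v];
    propagated_at[v] = dv;
    for (int h : M.vout[v]) {
      try_update(M.to(h), dv + M.elen[h], Prov{3, M.twin[h], 0, 0});
      // relax the third face edge too: it may be a boundary edge whose
      // outgoing twin does not exist
      try_update(M.apx(h), dv + M.elen[M.prv(h)], Prov{3, M.prv(h), 0, 0});
    }
    double tot = M.angsum[v];
    double eps = tot - 2 * M_PI;
    double wdt = eps + 2 * SHADOW_PAD;
    bool full = (v == srcv) || M.vbnd[v] || prov[v].role < 0 ||
                wdt >= 2 * M_PI;
    double s0 = 0;
    if (!full) {
      s0 = psi_from_prov(prov[v]) + M_PI - SHADOW_PAD;
      s0 -= tot * std::floor(s0 / tot);
    }
    for (int h : M.vout[v]) {
      int e = M.nxt(h);  // opposite edge, runs to(h) -> apex
      int t = M.twin[e];
      if (t < 0) continue;
      if (full) {
        // full coverage: from(t) is the far endpoint; d0 = |v - from(t)|
        push_window(t, 0.0, M.elen[t], M.elen[M.prv(h)], M.elen[h], dv);
        continue;
      }
      // clip the face's angular span [theta, theta + hang] to the shadow
      double th = he_theta[h], fa = hang[h];
      for (double shift : {-tot, 0.0, tot}) {
        double l0 = std::max(th, s0 + shift);
        double l1 = std::min(th + fa, s0 + wdt + shift);
        if (l1 - l0 > 1e-12) emit_clipped(h, l0 - th, l1 - th, dv);
      }
    }
  }

  // Window from vertex from(h) into face(h), restricted to local angles
  // [a0, a1] measured from the spoke h.
  void emit_clipped(int h, double a0, double a1, double dv) {
    int e = M.nxt(h);
    int t = M.twin[e];
    double r0 = M.elen[h], r1 = M.elen[M.prv(h)];
    double fa = hang[h], Lo = M.elen[e];
    double Px = r0, Py = 0;
    double Qx = r1 * std::cos(fa), Qy = r1 * std::sin(fa);
    double Dx = Qx - Px, Dy = Qy - Py;
    auto hit = [&](double a) {
      double ux = std::cos(a), uy = std::sin(a);
      double den = Dx * uy - Dy * ux;
      if (std::fabs(den) < 1e-300) return a > fa / 2 ? 1.0 : 0.0;
      double tt = (-Px * uy + Py * ux) / den;
      return std::max(0.0, std::min(1.0, tt));
    };
    double t0 = hit(a0), t1 = hit(a1);
    double z0x = Px + t0 * Dx, z0y = Py + t0 * Dy;
    double z1x = Px + t1 * Dx, z1y = Py + t1 * Dy;
    // child frame runs apex -> to(h): b measured from the apex end
    push_window(t, (1 - t1) * Lo, (1 - t0) * Lo, std::hypot(z1x, z1y),
                std::hypot(z0x, z0y), dv);
  }

  // Pseudo-source planar position from window parameters (py <= 0).
  static void pseudo_source(double b0, double b1, double d0, double d1,
                            double& px, double& py) {
    px = (d0 * d0 - d1 * d1 + b1 * b1 - b0 * b0) / (2 * (b1 - b0));
    double py2 = d0 * d0 - (px - b0) * (px - b0);
    py = -std::sqrt(std::max(0.0, py2));
  }

  // A window is dominated if its distance exceeds the bound
  // min(dist[A] + b, dist[B] + L - b) everywhere on its interval. The
  // difference is monotone on each linear piece of the bound, so the
  // interval minimum is attained at the piece break or an interval end.
  bool dominated(int h, double b0, double b1, double d0, double d1,
                 double sigma) const {
    double L = M.elen[h];
    double dA = dist[M.from(h)], dB = dist[M.to(h)];
    if (dA == inf() && dB == inf()) return false;
    double px, py;
    pseudo_source(b0, b1, d0, d1, px, py);
    auto wval = [&](double b) { return sigma + std::hypot(b - px, py); };
    double margin = EPSW * (sigma + L + d0 + d1);
    if (dA == inf())
      return wval(b0) > dB + (L - b0) + margin;
    if (dB == inf())
      return wval(b1) > dA + b1 + margin;
    double bstar = 0.5 * (dB - dA + L);
    double r1 = std::min(b1, std::max(b0, bstar));  // min of piece-1 part
    double l2 = std::max(b0, std::min(b1, bstar));  // min of piece-2 part
    double h1 = wval(r1) - (dA + r1);
    double h2 = wval(l2) - (dB + (L - l2));
    return std::min(h1, h2) > margin;
  }

  void push_window(int h, double b0, double b1, double d0, double d1,
                   double sigma) {
    double L = M.elen[h];
    if (b0 < 0) b0 = 0;
    if (b1 > L) b1 = L;
    if (b1 - b0 < EPSW * L) return;
    double px, py;
    pseudo_source(b0, b1, d0, d1, px, py);
    // vertex capture at the interval ends, with the exact unfolded distance
    if (b0 < EPSV * L)
      try_update(M.from(h), sigma + std::hypot(px, py), Prov{1, h, px, py});
    if (b1 > L * (1 - EPSV))
      try_update(M.to(h), sigma + std::hypot(L - px, py), Prov{2, h, px, py});
    if (dominated(h, b0, b1, d0, d1, sigma)) return;
    double dmin = (px >= b0 && px <= b1) ? -py : std::min(d0, d1);
    q.push(Event{sigma + dmin, 0, h, b0, b1, d0, d1, sigma});
  }

  // Unfold face(h), split the window's wedge at the apex if it contains it,
  // and emit clipped child windows on the two far halfedges.
  void propagate_window(const Event& w) {
    int h = w.id;
    double L = M.elen[h];
    double cA = M.elen[M.prv(h)];  // |A - C|
    double cB = M.elen[M.nxt(h)];  // |B - C|
    double cx = (L * L + cA * cA - cB * cB) / (2 * L);
    double cy = std::sqrt(std::max(0.0, cA * cA - cx * cx));
    double px, py;
    pseudo_source(w.b0, w.b1, w.d0, w.d1, px, py);
    if (py > -EPSW * L) py = -EPSW * L;  // degenerate collinear pseudo-source

    double u0x = w.b0 - px, u0y = -py;   // left wedge ray
    double u1x = w.b1 - px, u1y = -py;   // right wedge ray
    double wcx = cx - px, wcy = cy - py; // toward apex
    double cr0 = u0x * wcy - u0y * wcx;  // >0: apex strictly left of left ray
    double cr1 = u1x * wcy - u1y * wcx;  // <0: apex strictly right of right ray
    double tol = EPSW * L * (std::fabs(wcx) + std::fabs(wcy) + L);

    int tCA = M.twin[M.prv(h)];  // child frame A -> C, length cA
    int tBC = M.twin[M.nxt(h)];  // child frame C -> B, length cB

    // intersection parameter t of ray ps + s*u with segment P + t*(Q-P)
    auto seg_t = [&](double ux, double uy, double Px, double Py, double Qx,
                     double Qy) {
      double Dx = Qx - Px, Dy = Qy - Py;
      double den = Dx * uy - Dy * ux;
      if (std::fabs(den) < 1e-300) return std::numeric_limits<double>::quiet_NaN();
      return ((px - Px) * uy - (py - Py) * ux) / den;
    };
    auto clamp01 = [](double t) {
      if (std::isnan(t)) return 0.0;
      return std::max(0.0, std::min(1.0, t));
    };

    // apex capture: generous angular tolerance, exact unfolded distance
    double dC = std::sqrt(wcx * wcx + wcy * wcy);
    double n0 = std::hypot(u0x, u0y) * dC, n1 = std::hypot(u1x, u1y) * dC;
    if (cr0 <= EPSV * n0 && cr1 >= -EPSV * n1)
      try_update(M.apx(h), w.sigma + dC, Prov{0, h, px, py});

    if (cr0 <= tol && cr1 >= -tol) {
      // apex inside the wedge: split into two children
      if (tCA >= 0) {
        // left ray exits segment A(0,0) -> C(cx,cy); child covers exit..C
        double t = clamp01(seg_t(u0x, u0y, 0, 0, cx, cy));
        double zx = t * cx, zy = t * cy;
        double bz = t * cA;
        double dz = std::hypot(zx - px, zy - py);
        push_window(tCA, bz, cA, dz, dC, w.sigma);
      }
      if (tBC >= 0) {
        // right ray exits segment B(L,0) -> C; child (frame C -> B) covers C..exit
        double t = clamp01(seg_t(u1x, u1y, L, 0, cx, cy));
        double zx = L + t * (cx - L), zy = t * cy;
        double bz = (1 - t) * cB;  // distance from C along C->B
        double dz = std::hypot(zx - px, zy - py);
        push_window(tBC, 0.0, bz, dC, dz, w.sigma);
      }
    } else if (cr0 > tol) {
      // whole wedge right of the apex: both rays exit B -> C
      if (tBC >= 0) {
        double t0 = clamp01(seg_t(u0x, u0y, L, 0, cx, cy));
        double t1 = clamp01(seg_t(u1x, u1y, L, 0, cx, cy));
        double z0x = L + t0 * (cx - L), z0y = t0 * cy;
        double z1x = L + t1 * (cx - L), z1y = t1 * cy;
        // frame C -> B: b = distance from C = (1 - t) * cB; left ray nearer C
        double bz0 = (1 - t0) * cB, bz1 = (1 - t1) * cB;
        double dz0 = std::hypot(z0x - px, z0y - py);
        double dz1 = std::hypot(z1x - px, z1y - py);
        push_window(tBC, bz0, bz1, dz0, dz1, w.sigma);
      }
    } else {
      // whole wedge left of the apex: both rays exit A -> C
      if (tCA >= 0) {
        double t0 = clamp01(seg_t(u0x, u0y, 0, 0, cx, cy));
        double t1 = clamp01(seg_t(u1x, u1y, 0, 0, cx, cy));
        double z0x = t0 * cx, z0y = t0 * cy;
        double z1x = t1 * cx, z1y = t1 * cy;
        // frame A -> C: b = t * cA; the left ray exits nearer A
        double bz0 = t0 * cA, bz1 = t1 * cA;
        double dz0 = std::hypot(z0x - px, z0y - py);
        double dz1 = std::hypot(z1x - px, z1y - py);
        push_window(tCA, bz0, bz1, dz0, dz1, w.sigma);
      }
    }
  }
};

void dijkstra_edges(const HEMesh& M, int src, double* out) {
  std::vector<double> dist(M.nv, std::numeric_limits<double>::infinity());
  using QE = std::pair<double, int>;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> q;
  dist[src] = 0;
  q.push({0.0, src});
  while (!q.empty()) {
    auto [d, v] = q.top();
    q.pop();
    if (d > dist[v]) continue;
    for (int h : M.vout[v]) {
      int u = M.to(h);
      double nd = d + M.elen[h];
      if (nd < dist[u]) {
        dist[u] = nd;
        q.push({nd, u});
      }
    }
  }
  for (int v = 0; v < M.nv; ++v) out[v] = dist[v];
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_geodesic_single(NumericMatrix V, IntegerMatrix F, int source,
                                  std::string method) {
  HEMesh M;
  build_hemesh(V, F, M);
  if (source < 1 || source > M.nv) stop("source vertex out of range");
  NumericVector out(M.nv);
  if (method == "vtp") {
    GeoSolver s(M);
    s.run(source - 1, out.begin());
  } else if (method == "dijkstra") {
    dijkstra_edges(M, source - 1, out.begin());
  } else {
    stop("unknown geodesic method '%s'", method.c_str());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_geodesic_multi(NumericMatrix V, IntegerMatrix F,
                                 IntegerVector sources, std::string method) {
  HEMesh M;
  build_hemesh(V, F, M);
  NumericMatrix out(sources.size(), M.nv);
  GeoSolver s(M);
  std::vector<double> buf(M.nv);
  for (int i = 0; i < sources.size(); ++i) {
    int src = sources[i];
    if (src < 1 || src > M.nv) stop("source vertex out of range");
    if (method == "vtp")
      s.run(src - 1, buf.data());
    else
      dijkstra_edges(M, src - 1, buf.data());
    for (int v = 0; v < M.nv; ++v) out(i, v) = buf[v];
  }
  return out;
}

// Evaluate sorted displacement records: one geodesic call per distinct lower
// vertex serves its whole contiguous block.
// [[Rcpp::export]]
List cpp_evaluate_blocks(NumericMatrix V, IntegerMatrix F, IntegerVector vlo,
                         IntegerVector vhi, std::string method) {
  HEMesh M;
  build_hemesh(V, F, M);
  R_xlen_t n = vlo.size();
  if (vhi.size() != n) stop("v_lo and v_hi lengths differ");
  NumericVector out(n);
  GeoSolver s(M);
  std::vector<double> buf(M.nv);
  int calls = 0;
  R_xlen_t i = 0;
  while (i < n) {
    int src = vlo[i];
    if (i > 0 && src < vlo[i - 1]) stop("records are not sorted by v_lo");
    if (src < 1 || src > M.nv) stop("record references vertex %d out of range", src);
    if (method == "vtp")
      s.run(src - 1, buf.data());
    else
      dijkstra_edges(M, src - 1, buf.data());
    ++calls;
    while (i < n && vlo[i] == src) {
      int tgt = vhi[i];
      if (tgt < 1 || tgt > M.nv)
        stop("record references vertex %d out of range", tgt);
      out[i] = buf[tgt - 1];
      ++i;
    }
  }
  return List::create(_["distance"] = out, _["n_calls"] = calls);
}
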