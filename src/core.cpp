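// Computational core of the crypt engine:
//  - Bowyer-Watson Delaunay triangulation of the unrolled periodic crypt
//    (ghost replication in x, mirror ghosts at the base and above the top)
//    with clipped Voronoi areas,
//  - pairwise linear spring forces with minimum-image separation,
//  - batched fixed-step RK4 advance of the per-cell signalling + cycle ODEs.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tri {
  int v[3];   // vertex indices
  int n[3];   // neighbour triangle opposite vertex k (-1 = none)
  bool alive;
  double cx, cy, r2;  // circumcircle
};

struct Delaunay {
  const std::vector<double>& px;
  const std::vector<double>& py;
  std::vector<Tri> tris;
  int last_tri;
  // reusable scratch (epoch-marked) to avoid per-insert allocation
  std::vector<int> mark_;
  int epoch_;
  std::vector<int> cavity_, stack_;
  struct BEdge { int a, b, ext; };
  std::vector<BEdge> bedges_;
  struct Open { int vtx, tri; };
  std::vector<Open> open_;

  Delaunay(const std::vector<double>& x, const std::vector<double>& y)
    : px(x), py(y), last_tri(0), epoch_(0) {
    tris.reserve(12 * x.size());
    mark_.reserve(12 * x.size());
  }

  void circum(Tri& t) {
    double ax = px[t.v[0]], ay = py[t.v[0]];
    double bx = px[t.v[1]], by = py[t.v[1]];
    double cx = px[t.v[2]], cy = py[t.v[2]];
    double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
    double ux = ((ax * ax + ay * ay) * (by - cy) + (bx * bx + by * by) * (cy - ay) +
                 (cx * cx + cy * cy) * (ay - by)) / d;
    double uy = ((ax * ax + ay * ay) * (cx - bx) + (bx * bx + by * by) * (ax - cx) +
                 (cx * cx + cy * cy) * (bx - ax)) / d;
    t.cx = ux; t.cy = uy;
    double dx = ux - ax, dy = uy - ay;
    t.r2 = dx * dx + dy * dy;
  }

  inline bool in_circle(const Tri& t, double x, double y) const {
    double dx = x - t.cx, dy = y - t.cy;
    return dx * dx + dy * dy < t.r2 * (1.0 + 1e-12);
  }

  inline double orient(int a, int b, double x, double y) const {
    return (px[b] - px[a]) * (y - py[a]) - (py[b] - py[a]) * (x - px[a]);
  }

  // walk from last_tri toward (x, y); returns a triangle whose circumcircle
  // contains the point (the containing triangle when the walk succeeds).
  // Moves through the edge with the most negative orientation, avoiding
  // immediate backtracking, which prevents two-triangle cycles.
  int locate(double x, double y) {
    int t = last_tri, prev = -1;
    if (t < 0 || t >= (int)tris.size() || !tris[t].alive) t = -1;
    if (t >= 0) {
      for (int guard = 0; guard < (int)tris.size() + 8; ++guard) {
        const Tri& tr = tris[t];
        int best = -1;
        double worst = -1e-13;
        for (int k = 0; k < 3; ++k) {
          int a = tr.v[(k + 1) % 3], b = tr.v[(k + 2) % 3];
          double o = orient(a, b, x, y);
          if (o < worst && tr.n[k] != prev) { worst = o; best = tr.n[k]; }
        }
        if (best < 0) return t;  // inside (or stuck on hull edge)
        prev = t;
        t = best;
      }
    }
    // fallback: linear scan for any triangle whose circumcircle covers p
    for (int i = 0; i < (int)tris.size(); ++i)
      if (tris[i].alive && in_circle(tris[i], x, y)) return i;
    stop("point location failed (degenerate configuration)");
    return -1;
  }

  void insert(int ip) {
    double x = px[ip], y = py[ip];
    int t0 = locate(x, y);
    // cavity search (BFS over neighbours with circumcircle containing p)
    std::vector<int>& cavity = cavity_; cavity.clear();
    std::vector<int>& stack = stack_; stack.clear();
    ++epoch_;
    mark_.resize(tris.size() + 64, 0);
    if (!in_circle(tris[t0], x, y)) {
      // walk ended in a triangle not violating the circle (numerical edge
      // case): search its neighbours
      bool found = false;
      for (int k = 0; k < 3 && !found; ++k) {
        int nb = tris[t0].n[k];
        if (nb >= 0 && in_circle(tris[nb], x, y)) { t0 = nb; found = true; }
      }
      if (!found) {
        for (int i = 0; i < (int)tris.size() && !found; ++i)
          if (tris[i].alive && in_circle(tris[i], x, y)) { t0 = i; found = true; }
      }
      if (!found) stop("insertion failed: no conflicting triangle");
    }
    stack.push_back(t0); mark_[t0] = epoch_;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int k = 0; k < 3; ++k) {
        int nb = tris[t].n[k];
        if (nb >= 0 && mark_[nb] != epoch_ && tris[nb].alive && in_circle(tris[nb], x, y)) {
          mark_[nb] = epoch_; stack.push_back(nb);
        }
      }
    }
    // boundary edges of the cavity: (a, b) with external neighbour
    std::vector<BEdge>& bedges = bedges_; bedges.clear();
    for (int t : cavity) {
      for (int k = 0; k < 3; ++k) {
        int nb = tris[t].n[k];
        if (nb < 0 || mark_[nb] != epoch_) {
          BEdge e;
          e.a = tris[t].v[(k + 1) % 3];
          e.b = tris[t].v[(k + 2) % 3];
          e.ext = nb;
          bedges.push_back(e);
        }
      }
    }
    for (int t : cavity) tris[t].alive = false;
    // create new triangles (p, a, b), stitched to externals and each other
    std::vector<Open>& open_edge = open_;
    open_edge.clear();
    int first_new = -1;
    for (size_t be = 0; be < bedges.size(); ++be) {
      const BEdge& e = bedges[be];
      Tri nt;
      nt.v[0] = ip; nt.v[1] = e.a; nt.v[2] = e.b;
      // ensure CCW orientation
      double o = (px[e.a] - px[ip]) * (py[e.b] - py[ip]) -
                 (py[e.a] - py[ip]) * (px[e.b] - px[ip]);
      if (o < 0) std::swap(nt.v[1], nt.v[2]);
      nt.n[0] = e.ext;  // opposite p is the external edge
      nt.n[1] = -2; nt.n[2] = -2;  // to be stitched
      nt.alive = true;
      circum(nt);
      tris.push_back(nt);
      int idx = (int)tris.size() - 1;
      mark_.resize(tris.size() + 8, 0);
      if (first_new < 0) first_new = idx;
      // fix external neighbour back-pointer
      if (e.ext >= 0) {
        Tri& ex = tris[e.ext];
        for (int k = 0; k < 3; ++k) {
          int a = ex.v[(k + 1) % 3], b = ex.v[(k + 2) % 3];
          if ((a == e.a && b == e.b) || (a == e.b && b == e.a)) { ex.n[k] = idx; break; }
        }
      }
      // stitch around p: sides opposite v[1] (edge p-v[2]) and v[2] (edge p-v[1])
      Tri& me = tris[idx];
      for (int k = 1; k <= 2; ++k) {
        int other = me.v[k == 1 ? 2 : 1];
        int j = -1;
        for (size_t q = 0; q < open_edge.size(); ++q)
          if (open_edge[q].vtx == other) { j = open_edge[q].tri;
            open_edge[q] = open_edge.back(); open_edge.pop_back(); break; }
        if (j >= 0) {
          me.n[k] = j;
          Tri& tj = tris[j];
          for (int q = 1; q <= 2; ++q)
            if (tj.v[q == 1 ? 2 : 1] == other) tj.n[q] = idx;
        } else {
          Open o; o.vtx = other; o.tri = idx;
          open_edge.push_back(o);
        }
      }
    }
    if (!open_edge.empty()) stop("cavity stitching failed (degenerate input)");
    last_tri = first_new;
  }
};

inline double min_image(double dx, double Wc) {
  return dx - Wc * std::round(dx / Wc);
}

}  // namespace

// Periodic Delaunay adjacency and clipped Voronoi areas for the crypt band.
// x is periodic with period Wc; mirror ghosts are placed below the base
// (reflection across y = -0.025, slightly perturbed to break cocircular
// rectangles formed by clamped cells) and above y = ytop. Voronoi polygons
// are clipped to y in [0, ytop]; 'clipped' marks cells whose polygon touched
// either clip plane.
// [[Rcpp::export]]
List cpp_crypt_geometry(NumericVector x, NumericVector y, double Wc,
                        double ytop, double cutoff) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 cells");
  const double marg = std::max(2.5, cutoff + 1.0);
  std::vector<double> px, py;
  std::vector<int> src;
  px.reserve(4 * n); py.reserve(4 * n); src.reserve(4 * n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i] - Wc * std::floor(x[i] / Wc);
    px.push_back(xi); py.push_back(y[i]); src.push_back(i);
  }
  // mirror ghosts (small deterministic perturbation breaks exact cocircularity)
  for (int i = 0; i < n; ++i) {
    double pert = 1e-5 * std::sin(57.31 * px[i] + 13.7);
    if (py[i] < marg)
      { px.push_back(px[i]); py.push_back(-0.05 - py[i] + pert); src.push_back(i + n); }
    if (py[i] > ytop - marg)
      { px.push_back(px[i]); py.push_back(2.0 * ytop - py[i] + 0.05 - pert); src.push_back(i + n); }
  }
  // x-replication of everything near the wrap
  int m0 = (int)px.size();
  for (int j = 0; j < m0; ++j) {
    if (px[j] < marg) { px.push_back(px[j] + Wc); py.push_back(py[j]); src.push_back(src[j]); }
    if (px[j] > Wc - marg) { px.push_back(px[j] - Wc); py.push_back(py[j]); src.push_back(src[j]); }
  }
  const int m = (int)px.size();
  // super-triangle
  double xmin = 1e30, xmax = -1e30, ymin = 1e30, ymax = -1e30;
  for (int j = 0; j < m; ++j) {
    xmin = std::min(xmin, px[j]); xmax = std::max(xmax, px[j]);
    ymin = std::min(ymin, py[j]); ymax = std::max(ymax, py[j]);
  }
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double span = std::max(xmax - xmin, ymax - ymin) * 64.0 + 64.0;
  px.push_back(cx - 2.0 * span); py.push_back(cy - span); src.push_back(-1);
  px.push_back(cx + 2.0 * span); py.push_back(cy - span); src.push_back(-1);
  px.push_back(cx);              py.push_back(cy + 2.0 * span); src.push_back(-1);

  Delaunay dt(px, py);
  std::vector<int> order(m);
  for (int j = 0; j < m; ++j) order[j] = j;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    int ba = (int)std::floor(py[a]), bb = (int)std::floor(py[b]);
    if (ba != bb) return ba < bb;
    double xa = (ba & 1) ? -px[a] : px[a];
    double xb = (bb & 1) ? -px[b] : px[b];
    return xa < xb;
  });
  Tri st;
  st.v[0] = m; st.v[1] = m + 1; st.v[2] = m + 2;
  // ensure CCW
  {
    double o = (px[m + 1] - px[m]) * (py[m + 2] - py[m]) -
               (py[m + 1] - py[m]) * (px[m + 2] - px[m]);
    if (o < 0) std::swap(st.v[1], st.v[2]);
  }
  st.n[0] = st.n[1] = st.n[2] = -1;
  st.alive = true;
  dt.circum(st);
  dt.tris.push_back(st);
  for (int j = 0; j < m; ++j) dt.insert(order[j]);

  // collect edges between real cells (at least one true real entry index < n)
  std::vector<long long> ecodes;
  std::vector<std::vector<int> > fans(n);
  for (int t = 0; t < (int)dt.tris.size(); ++t) {
    const Tri& tr = dt.tris[t];
    if (!tr.alive) continue;
    if (tr.v[0] >= m || tr.v[1] >= m || tr.v[2] >= m) continue;  // touches super
    for (int k = 0; k < 3; ++k) {
      int a = tr.v[k];
      if (a < n) fans[a].push_back(t);
      int b = tr.v[(k + 1) % 3];
      if (a >= n && b >= n) continue;
      int ra = src[a] >= n ? src[a] - n : src[a];
      int rb = src[b] >= n ? src[b] - n : src[b];
      bool ghost_a = src[a] >= n, ghost_b = src[b] >= n;
      if (ghost_a || ghost_b) continue;  // mirror ghosts carry no springs
      if (ra == rb) continue;
      if (a >= n && b >= n) continue;
      int lo = std::min(ra, rb), hi = std::max(ra, rb);
      double dx = min_image(x[lo] - x[hi], Wc);
      double dy = y[lo] - y[hi];
      if (std::sqrt(dx * dx + dy * dy) <= cutoff)
        ecodes.push_back((long long)lo * (long long)n + hi);
    }
  }
  std::sort(ecodes.begin(), ecodes.end());
  ecodes.erase(std::unique(ecodes.begin(), ecodes.end()), ecodes.end());
  IntegerMatrix edges((int)ecodes.size(), 2);
  for (size_t r = 0; r < ecodes.size(); ++r) {
    edges(r, 0) = (int)(ecodes[r] / n) + 1; edges(r, 1) = (int)(ecodes[r] % n) + 1;
  }

  // Voronoi areas: polygon of circumcenters around each real cell, clipped
  NumericVector areas(n);
  LogicalVector clipped(n);
  std::vector<std::pair<double, std::pair<double, double> > > poly;
  for (int i = 0; i < n; ++i) {
    if (fans[i].empty()) { areas[i] = NA_REAL; clipped[i] = true; continue; }
    poly.clear();
    for (size_t q = 0; q < fans[i].size(); ++q) {
      const Tri& tr = dt.tris[fans[i][q]];
      double ang = std::atan2(tr.cy - py[i], tr.cx - px[i]);
      poly.push_back(std::make_pair(ang, std::make_pair(tr.cx, tr.cy)));
    }
    std::sort(poly.begin(), poly.end());
    // Sutherland-Hodgman clip against y >= 0 and y <= ytop
    std::vector<std::pair<double, double> > P, Q;
    for (size_t q = 0; q < poly.size(); ++q) P.push_back(poly[q].second);
    bool was_clipped = false;
    for (int pass = 0; pass < 2; ++pass) {
      Q.clear();
      size_t np = P.size();
      for (size_t q = 0; q < np; ++q) {
        std::pair<double, double> A = P[q], B = P[(q + 1) % np];
        double da = (pass == 0) ? A.second : (ytop - A.second);
        double db = (pass == 0) ? B.second : (ytop - B.second);
        // only base-plane clipping flags the cell: areas truncated at the
        // crypt wall are not a crowding signal, whereas the top plane caps
        // the open orifice and leaves areas meaningful
        if (da >= 0) Q.push_back(A); else if (pass == 0) was_clipped = true;
        if ((da < 0) != (db < 0)) {
          double s = da / (da - db);
          Q.push_back(std::make_pair(A.first + s * (B.first - A.first),
                                     A.second + s * (B.second - A.second)));
          if (pass == 0) was_clipped = true;
        }
      }
      P = Q;
      if (P.empty()) break;
    }
    double area = 0.0;
    for (size_t q = 0; q < P.size(); ++q) {
      size_t q2 = (q + 1) % P.size();
      area += P[q].first * P[q2].second - P[q2].first * P[q].second;
    }
    areas[i] = 0.5 * std::fabs(area);
    clipped[i] = was_clipped;
  }
  return List::create(_["edges"] = edges, _["areas"] = areas,
                      _["clipped"] = clipped);
}

// Linear (Hookean) spring forces along minimum-image separations.
// [[Rcpp::export]]
NumericMatrix cpp_spring_forces(NumericMatrix pos, IntegerMatrix edges,
                                NumericVector rest, double mu, double Wc) {
  const int n = pos.nrow(), ne = edges.nrow();
  NumericMatrix F(n, 2);
  for (int e = 0; e < ne; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double dx = min_image(pos(j, 0) - pos(i, 0), Wc);
    double dy = pos(j, 1) - pos(i, 1);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < 1e-12) stop("coincident cell centres");
    double f = mu * (d - rest[e]) / d;  // >0 stretched: pulls i toward j
    F(i, 0) += f * dx; F(i, 1) += f * dy;
    F(j, 0) -= f * dx; F(j, 1) -= f * dy;
  }
  return F;
}

namespace {

// signalling parameter vector layout (see .sp_vec in R)
enum { SX, DX_OFF, DX_ON, PXD, DDX_OFF, DDX_ON, DD_OFF, DD_ON, SC, DCc, PU,
       KC, DU, SA, DA_, PA, DCA, TTOT, PT, DCT, SY, KY, DY, PHmax, KH, DH,
       SP_LEN };
// cycle parameter vector layout (see .cp_vec in R)
enum { K1, K2, K3, K16, K34, K43, K61, K23, KP, Aa, J11, J12, J13, J61, J62,
       J63, KM1, KM2, KM4, PHI_R, PHI_E, PHI_DI, PHI_DA, PHI_RP, TAU, MUCT,
       CP_LEN };

inline void rhs_sig(const double* yv, double* dy, const double* sp,
                    double W, double pHhat, bool mutant) {
  // signalling: X D A CA CC CT CU CH Y
  double X = yv[0], D = yv[1], A = yv[2], CA = yv[3], CC = yv[4];
  double CT = yv[5], CU = yv[6], CH = yv[7], Y = yv[8];
  double dX = sp[DX_OFF] + W * (sp[DX_ON] - sp[DX_OFF]);
  double dDX = sp[DDX_OFF] + W * (sp[DDX_ON] - sp[DDX_OFF]);
  double dD = sp[DD_OFF] + W * (sp[DD_ON] - sp[DD_OFF]);
  double Tf = sp[TTOT] - CT; if (Tf < 0) Tf = 0;
  double J_mark = mutant ? 0.0 : sp[PU] * D * CC / (sp[KC] + CC);
  double J_hippo = pHhat * CC / (sp[KH] + CC);
  double J_adh = sp[PA] * A * CC - sp[DCA] * CA;
  double J_tcf = sp[PT] * Tf * CC - sp[DCT] * CT;
  dy[0] = sp[SX] - dX * X - sp[PXD] * X + dDX * D;
  dy[1] = sp[PXD] * X - (dDX + dD) * D;
  dy[2] = sp[SA] - sp[DA_] * A - J_adh;
  dy[3] = J_adh;
  dy[4] = sp[SC] - sp[DCc] * CC - J_mark - J_adh - J_tcf - J_hippo;
  dy[5] = J_tcf;
  dy[6] = J_mark - sp[DU] * CU;
  dy[7] = J_hippo - sp[DH] * CH;
  dy[8] = sp[SY] * CT / (sp[KY] + CT) - sp[DY] * Y;
}

inline void rhs_cyc(const double* yv, double* dy, const double* cp,
                    double CT) {
  // cycle: pRb E2F1 CycDi CycDa pRbP, mitogen m = mu_ct * CT
  double R = yv[0], E = yv[1], Di = yv[2], Da = yv[3], Rp = yv[4];
  double mtg = cp[MUCT] * CT;
  double act = Da / (cp[KM4] + Da);
  dy[0] = cp[TAU] * (cp[K1] * (E / (cp[KM1] + E)) * (cp[J11] / (cp[J11] + R)) *
            (cp[J61] / (cp[J61] + Rp)) - cp[K16] * R * Da + cp[K61] * Rp -
            cp[PHI_R] * R);
  dy[1] = cp[TAU] * (cp[KP] + cp[K2] * ((cp[Aa] * cp[Aa] + E * E) /
            (cp[KM2] * cp[KM2] + E * E)) * (cp[J12] / (cp[J12] + R)) *
            (cp[J62] / (cp[J62] + Rp)) - cp[PHI_E] * E);
  dy[2] = cp[TAU] * (cp[K3] * mtg + cp[K23] * E * (cp[J13] / (cp[J13] + R)) *
            (cp[J63] / (cp[J63] + Rp)) + cp[K43] * Da - cp[K34] * Di * act -
            cp[PHI_DI] * Di);
  dy[3] = cp[TAU] * (cp[K34] * Di * act - (cp[K43] + cp[PHI_DA]) * Da);
  dy[4] = cp[TAU] * (cp[K16] * R * Da - cp[K61] * Rp - cp[PHI_RP] * Rp);
}

}  // namespace

// Advance all cells' signalling (9, stiff: nsub_sig RK4 substeps) and cycle
// (5, non-stiff: nsub_cyc RK4 substeps with linearly interpolated CT) ODEs
// by dt. The coupling is one-way (CT drives the cycle), so the signalling
// block is advanced first. Returns new matrices (inputs untouched).
// [[Rcpp::export]]
List cpp_advance_cells(NumericMatrix sig, NumericMatrix cyc, NumericVector W,
                       NumericVector pHhat, LogicalVector mutant,
                       NumericVector spv, NumericVector cpv,
                       double dt, int nsub_sig, int nsub_cyc) {
  const int n = sig.nrow();
  if (sig.ncol() != 9 || cyc.ncol() != 5) stop("bad state dimensions");
  if (spv.size() != SP_LEN || cpv.size() != CP_LEN) stop("bad parameter vectors");
  NumericMatrix sig2 = clone(sig), cyc2 = clone(cyc);
  const double* sp = REAL(spv);
  const double* cp = REAL(cpv);
  const double hs = dt / nsub_sig;
  const double hc = dt / nsub_cyc;
  double yv[9], k1[9], k2[9], k3[9], k4[9], tmp[9];
  double cv[5], c1[5], c2[5], c3[5], c4[5], ctm[5];
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < 9; ++q) yv[q] = sig2(i, q);
    bool mut = mutant[i];
    double Wi = W[i], pHi = pHhat[i];
    double CT0 = yv[5];
    for (int s = 0; s < nsub_sig; ++s) {
      rhs_sig(yv, k1, sp, Wi, pHi, mut);
      for (int q = 0; q < 9; ++q) tmp[q] = std::max(yv[q] + 0.5 * hs * k1[q], 0.0);
      rhs_sig(tmp, k2, sp, Wi, pHi, mut);
      for (int q = 0; q < 9; ++q) tmp[q] = std::max(yv[q] + 0.5 * hs * k2[q], 0.0);
      rhs_sig(tmp, k3, sp, Wi, pHi, mut);
      for (int q = 0; q < 9; ++q) tmp[q] = std::max(yv[q] + hs * k3[q], 0.0);
      rhs_sig(tmp, k4, sp, Wi, pHi, mut);
      for (int q = 0; q < 9; ++q) {
        yv[q] += hs / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
        if (yv[q] < 0) yv[q] = 0;
        if (!std::isfinite(yv[q])) stop("non-finite signalling state (cell %d)", i + 1);
      }
    }
    double CT1 = yv[5];
    for (int q = 0; q < 5; ++q) cv[q] = cyc2(i, q);
    for (int s = 0; s < nsub_cyc; ++s) {
      double t0 = (double)s / nsub_cyc, tm = (s + 0.5) / (double)nsub_cyc,
             t1 = (s + 1.0) / nsub_cyc;
      double ct_a = CT0 + (CT1 - CT0) * t0;
      double ct_m = CT0 + (CT1 - CT0) * tm;
      double ct_b = CT0 + (CT1 - CT0) * t1;
      rhs_cyc(cv, c1, cp, ct_a);
      for (int q = 0; q < 5; ++q) ctm[q] = std::max(cv[q] + 0.5 * hc * c1[q], 0.0);
      rhs_cyc(ctm, c2, cp, ct_m);
      for (int q = 0; q < 5; ++q) ctm[q] = std::max(cv[q] + 0.5 * hc * c2[q], 0.0);
      rhs_cyc(ctm, c3, cp, ct_m);
      for (int q = 0; q < 5; ++q) ctm[q] = std::max(cv[q] + hc * c3[q], 0.0);
      rhs_cyc(ctm, c4, cp, ct_b);
      for (int q = 0; q < 5; ++q) {
        cv[q] += hc / 6.0 * (c1[q] + 2.0 * c2[q] + 2.0 * c3[q] + c4[q]);
        if (cv[q] < 0) cv[q] = 0;
        if (!std::isfinite(cv[q])) stop("non-finite cycle state (cell %d)", i + 1);
      }
    }
    for (int q = 0; q < 9; ++q) sig2(i, q) = yv[q];
    for (int q = 0; q < 5; ++q) cyc2(i, q) = cv[q];
  }
  return List::create(_["sig"] = sig2, _["cyc"] = cyc2);
}
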