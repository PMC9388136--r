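// Brownian-dynamics core for microtubule networks with motile cross-linkers.
//
// Layout of one time step (fixed order, guaranteeing seed reproducibility):
//   nucleation/growth -> force assembly (spring, steric; loads recorded)
//   -> vertex update (explicit drift for soft forces, exact
//   Ornstein-Uhlenbeck update for the stiff linearized bending term plus
//   thermal noise, in per-filament bending-mode space) -> segment-length
//   constraint projection -> Z reflection -> linker kinetics (unbind, move,
//   bind; rates from pre-update loads) -> free-linker diffusion.
//
// Coordinates are never wrapped in X/Y (trajectories stay unwrapped for
// displacement analysis); all pair interactions use the minimum-image
// displacement. Z is reflective.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstring>
#include <cstdint>
#include <chrono>
using namespace Rcpp;

// phase timing diagnostics (returned by engine_run)
static double g_time[8];
struct PhaseTimer {
  int slot;
  std::chrono::steady_clock::time_point t0;
  explicit PhaseTimer(int s) : slot(s), t0(std::chrono::steady_clock::now()) {}
  ~PhaseTimer() {
    g_time[slot] += std::chrono::duration<double>(
        std::chrono::steady_clock::now() - t0).count();
  }
};

static const double SITE = 0.008; // lattice spacing, um

// ------------------------------------------------------------------ RNG ---
// xoshiro256++ with splitmix64 seeding; normals by Marsaglia polar method.
struct Xo {
  uint64_t s[4];
  bool have;
  double cache;
  Xo() : have(false), cache(0) { s[0] = s[1] = s[2] = s[3] = 0; }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  void seed(uint64_t x) {
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    have = false;
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    if (have) { have = false; return cache; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    cache = v * f; have = true;
    return u * f;
  }
  // Knuth sampler given L = exp(-mu)
  int poissonL(double L) {
    double p = unif();
    int k = 0;
    while (p > L) { k++; p *= unif(); }
    return k;
  }
  int poisson(double mu) {
    if (mu <= 0) return 0;
    if (mu < 30.0) return poissonL(std::exp(-mu));
    double x = mu + std::sqrt(mu) * normal() + 0.5;
    return x < 0 ? 0 : (int)x;
  }
  // steps until the first success of a per-step Bernoulli(p) process
  int geom(double p) {
    if (p >= 1.0) return 1;
    if (p <= 0.0) return 1 << 30;
    double k = std::floor(std::log(unif()) / std::log1p(-p));
    if (k > 1e9) k = 1e9;
    return 1 + (int)k;
  }
};

// -------------------------------------------- small symmetric eigensolver --
// Cyclic Jacobi; A (n x n, row-major) destroyed; Q column eigenvectors.
static void jacobi_eigen(std::vector<double> A, int n,
                         std::vector<double>& Q, std::vector<double>& ev) {
  Q.assign(n * n, 0.0);
  for (int i = 0; i < n; i++) Q[i * n + i] = 1.0;
  for (int sweep = 0; sweep < 100; sweep++) {
    double off = 0;
    for (int p = 0; p < n; p++)
      for (int q = p + 1; q < n; q++) off += A[p * n + q] * A[p * n + q];
    if (off < 1e-24) break;
    for (int p = 0; p < n; p++) {
      for (int q = p + 1; q < n; q++) {
        double apq = A[p * n + q];
        if (std::fabs(apq) < 1e-18) continue;
        double theta = (A[q * n + q] - A[p * n + p]) / (2.0 * apq);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < n; k++) {
          double akp = A[k * n + p], akq = A[k * n + q];
          A[k * n + p] = c * akp - s * akq;
          A[k * n + q] = s * akp + c * akq;
        }
        for (int k = 0; k < n; k++) {
          double apk = A[p * n + k], aqk = A[q * n + k];
          A[p * n + k] = c * apk - s * aqk;
          A[q * n + k] = s * apk + c * aqk;
        }
        for (int k = 0; k < n; k++) {
          double qkp = Q[k * n + p], qkq = Q[k * n + q];
          Q[k * n + p] = c * qkp - s * qkq;
          Q[k * n + q] = s * qkp + c * qkq;
        }
      }
    }
  }
  ev.resize(n);
  for (int i = 0; i < n; i++) ev[i] = A[i * n + i];
}

// ------------------------------------------------------------- structures --
struct Unit {
  bool motor;
  double dir;   // +1 toward plus, -1 toward minus (motors)
  double vm, fs, D, kon, range, koff0, funb;
  bool release; // end policy
  // precomputed per time step (parse_state): binding and zero-load
  // unbinding probabilities, lattice rate, Knuth thresholds at zero load
  double pbind, poff0, r0, L_hop0, L_step0;
};
struct LType { Unit u[2]; double k, e; };

struct Fil {
  std::vector<double> v; // 3*nv: x0,y0,z0,x1,...  vertex 0 = minus end
  int nv;
  double alpha, last_rest;
  double length(double lseg) const { return (nv - 2) * lseg + last_rest; }
};

struct Lnk {
  int type;
  int fil[2];      // 0-based filament id, -1 unbound
  double absc[2];
  double pos[3];   // complex position when fully unbound
  // exact event-skip bookkeeping: steps until each unbound unit's next
  // binding attempt (geometric), and accumulated free-diffusion steps not
  // yet applied to pos (flushed in one Gaussian jump at attempt time)
  int try_in[2];
  int diff_accum;
};

struct Eng {
  double Lx, Ly, Lz, dt, kBT, gamV, gamL, kSter, dSter, kappa, lseg;
  double tol_constraint;
  double time_;
  double omega, poly;
  bool has_growth;
  double alpha0, sdfac, clipLo, clipHi, nucRate, growthUntil, initLen;
  std::vector<double> seedp; // 3*ns
  std::vector<int> seedUsed;
  std::vector<Fil> fils;
  std::vector<LType> types;
  std::vector<Lnk> lnks;
  Xo rng;
  // per-nv OU cache: Q (nv*nv), decay c_k, noise s_k
  std::map<int, std::vector<double>> cQ, cC, cS;
  // scratch per step
  std::vector<std::vector<double>> F; // per-fil forces, same layout as v
  // per-vertex attached soft-force stiffness (springs + steric), used for
  // the diagonally implicit drift: a vertex carrying total stiffness K
  // moves by F dt / (gamma + K dt), which is unconditionally stable no
  // matter how many cross-linkers load it, and consistent as dt -> 0
  std::vector<std::vector<double>> Kv;
  std::vector<double> loadPar[2];     // per-linker projected load per unit
  std::vector<double> loadMag;        // per-linker spring force magnitude

  double wrapdx(double d) const { return d - Lx * std::floor(d / Lx + 0.5); }
  double wrapdy(double d) const { return d - Ly * std::floor(d / Ly + 0.5); }
};

// anchor geometry: world position, segment index, weight, unit tangent
static void anchor_geom(const Eng& E, const Fil& f, double a,
                        double p[3], int& j, double& w, double t[3]) {
  int nseg = f.nv - 1;
  j = (int)(a / E.lseg);
  if (j > nseg - 1) j = nseg - 1;
  if (j < 0) j = 0;
  double rest = (j == nseg - 1) ? f.last_rest : E.lseg;
  double local = a - j * E.lseg;
  w = local / rest;
  if (w < 0) w = 0;
  if (w > 1) w = 1;
  const double* v0 = &f.v[3 * j];
  const double* v1 = &f.v[3 * (j + 1)];
  double n2 = 0;
  for (int c = 0; c < 3; c++) {
    p[c] = v0[c] + w * (v1[c] - v0[c]);
    t[c] = v1[c] - v0[c];
    n2 += t[c] * t[c];
  }
  double nn = std::sqrt(n2);
  if (nn > 0) for (int c = 0; c < 3; c++) t[c] /= nn;
}

static void ensure_ou(Eng& E, int nv) {
  if (E.cQ.count(nv)) return;
  int n = nv;
  std::vector<double> B(n * n, 0.0);
  // B = D2^T D2, D2 rows: e_i - 2 e_{i+1} + e_{i+2}
  for (int i = 0; i + 2 < n; i++) {
    int idx[3] = {i, i + 1, i + 2};
    double cf[3] = {1.0, -2.0, 1.0};
    for (int a = 0; a < 3; a++)
      for (int b = 0; b < 3; b++)
        B[idx[a] * n + idx[b]] += cf[a] * cf[b];
  }
  std::vector<double> Q, mu;
  jacobi_eigen(B, n, Q, mu);
  std::vector<double> C(n), S(n);
  double pref = E.kappa / (E.lseg * E.lseg * E.lseg);
  for (int k = 0; k < n; k++) {
    double m = mu[k];
    if (m > 1e-9) {
      double lam = pref * m / E.gamV;
      double c = std::exp(-lam * E.dt);
      C[k] = c;
      S[k] = std::sqrt(E.kBT / (pref * m) * (1.0 - c * c));
    } else {
      C[k] = 1.0;
      S[k] = std::sqrt(2.0 * E.kBT * E.dt / E.gamV);
    }
  }
  E.cQ[nv] = Q; E.cC[nv] = C; E.cS[nv] = S;
}

// ------------------------------------------------------------- cell grid --
struct Grid {
  int ncx, ncy;
  double cx, cy;
  std::vector<int> head, nxt;   // over segments
  std::vector<int> segFil, segIdx;
  std::vector<double> midw;     // wrapped midpoints, 3 per segment
  std::vector<double> halfLen;  // segment half-lengths
  std::vector<double> sdir;     // segment unit directions, 3 per segment
  void build(const Eng& E, double cell_min) {
    ncx = std::max(1, (int)std::floor(E.Lx / cell_min));
    ncy = std::max(1, (int)std::floor(E.Ly / cell_min));
    cx = E.Lx / ncx; cy = E.Ly / ncy;
    segFil.clear(); segIdx.clear(); midw.clear(); halfLen.clear();
    sdir.clear();
    for (size_t fi = 0; fi < E.fils.size(); fi++) {
      const Fil& f = E.fils[fi];
      for (int j = 0; j + 1 < f.nv; j++) {
        segFil.push_back((int)fi);
        segIdx.push_back(j);
        double mx = 0.5 * (f.v[3 * j] + f.v[3 * (j + 1)]);
        double my = 0.5 * (f.v[3 * j + 1] + f.v[3 * (j + 1) + 1]);
        double mz = 0.5 * (f.v[3 * j + 2] + f.v[3 * (j + 1) + 2]);
        mx -= E.Lx * std::floor(mx / E.Lx);
        my -= E.Ly * std::floor(my / E.Ly);
        midw.push_back(mx); midw.push_back(my); midw.push_back(mz);
        double hx = f.v[3 * (j + 1)] - f.v[3 * j];
        double hy = f.v[3 * (j + 1) + 1] - f.v[3 * j + 1];
        double hz = f.v[3 * (j + 1) + 2] - f.v[3 * j + 2];
        double hl = std::sqrt(hx * hx + hy * hy + hz * hz);
        halfLen.push_back(0.5 * hl);
        double inv = hl > 0 ? 1.0 / hl : 0.0;
        sdir.push_back(hx * inv);
        sdir.push_back(hy * inv);
        sdir.push_back(hz * inv);
      }
    }
    int ns = (int)segFil.size();
    head.assign(ncx * ncy, -1);
    nxt.assign(ns, -1);
    for (int s = 0; s < ns; s++) {
      int ix = std::min(ncx - 1, (int)(midw[3 * s] / cx));
      int iy = std::min(ncy - 1, (int)(midw[3 * s + 1] / cy));
      int c = iy * ncx + ix;
      nxt[s] = head[c];
      head[c] = s;
    }
  }
  // unique neighbor cells of the cell containing wrapped point (wx, wy)
  int neighbors(double wx, double wy, int out[9]) const {
    int ix = std::min(ncx - 1, std::max(0, (int)(wx / cx)));
    int iy = std::min(ncy - 1, std::max(0, (int)(wy / cy)));
    int n = 0;
    for (int dy = -1; dy <= 1; dy++) {
      for (int dx = -1; dx <= 1; dx++) {
        int jx = (ix + dx + ncx) % ncx;
        int jy = (iy + dy + ncy) % ncy;
        int c = jy * ncx + jx;
        bool seen = false;
        for (int k = 0; k < n; k++) if (out[k] == c) { seen = true; break; }
        if (!seen) out[n++] = c;
      }
    }
    return n;
  }
};

// closest points between segments p1-q1 and p2-q2 (Ericson); returns dist^2
static double seg_seg(const double p1[3], const double q1[3],
                      const double p2[3], const double q2[3],
                      double& s, double& t, double c1[3], double c2[3]) {
  double d1[3], d2[3], r[3];
  for (int c = 0; c < 3; c++) {
    d1[c] = q1[c] - p1[c]; d2[c] = q2[c] - p2[c]; r[c] = p1[c] - p2[c];
  }
  double a = d1[0]*d1[0]+d1[1]*d1[1]+d1[2]*d1[2];
  double e = d2[0]*d2[0]+d2[1]*d2[1]+d2[2]*d2[2];
  double f = d2[0]*r[0]+d2[1]*r[1]+d2[2]*r[2];
  if (a <= 1e-18 && e <= 1e-18) { s = t = 0; }
  else if (a <= 1e-18) { s = 0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = d1[0]*r[0]+d1[1]*r[1]+d1[2]*r[2];
    if (e <= 1e-18) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = d1[0]*d2[0]+d1[1]*d2[1]+d1[2]*d2[2];
      double den = a * e - b * b;
      s = (den > 1e-18) ? std::min(1.0, std::max(0.0, (b * f - c * e) / den)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double dd = 0;
  for (int c = 0; c < 3; c++) {
    c1[c] = p1[c] + s * d1[c];
    c2[c] = p2[c] + t * d2[c];
    double d = c2[c] - c1[c];
    dd += d * d;
  }
  return dd;
}

// ------------------------------------------------------ force assembly ----
// Spring forces of doubly bound linkers; records per-unit loads.
static void spring_forces(Eng& E) {
  size_t nl = E.lnks.size();
  E.loadPar[0].assign(nl, 0.0);
  E.loadPar[1].assign(nl, 0.0);
  E.loadMag.assign(nl, 0.0);
  for (size_t i = 0; i < nl; i++) {
    Lnk& L = E.lnks[i];
    if (L.fil[0] < 0 || L.fil[1] < 0) continue;
    const LType& T = E.types[L.type];
    double pa[3], pb[3], ta[3], tb[3], wa, wb;
    int ja, jb;
    anchor_geom(E, E.fils[L.fil[0]], L.absc[0], pa, ja, wa, ta);
    anchor_geom(E, E.fils[L.fil[1]], L.absc[1], pb, jb, wb, tb);
    double u[3] = {E.wrapdx(pb[0] - pa[0]), E.wrapdy(pb[1] - pa[1]),
                   pb[2] - pa[2]};
    double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    if (nu <= 1e-12) continue; // degenerate, measure zero: no force
    double coef = T.k * (1.0 - T.e / nu);
    double fa[3] = {coef * u[0], coef * u[1], coef * u[2]}; // on unit a
    // distribute to bounding vertices
    double* Fa = E.F[L.fil[0]].data();
    double* Fb = E.F[L.fil[1]].data();
    for (int c = 0; c < 3; c++) {
      Fa[3 * ja + c]       += (1.0 - wa) * fa[c];
      Fa[3 * (ja + 1) + c] += wa * fa[c];
      Fb[3 * jb + c]       -= (1.0 - wb) * fa[c];
      Fb[3 * (jb + 1) + c] -= wb * fa[c];
    }
    if (!E.Kv.empty()) {
      E.Kv[L.fil[0]][ja]     += T.k * (1.0 - wa);
      E.Kv[L.fil[0]][ja + 1] += T.k * wa;
      E.Kv[L.fil[1]][jb]     += T.k * (1.0 - wb);
      E.Kv[L.fil[1]][jb + 1] += T.k * wb;
    }
    double mag = std::fabs(coef) * nu;
    E.loadMag[i] = mag;
    for (int uidx = 0; uidx < 2; uidx++) {
      const Unit& U = E.types[L.type].u[uidx];
      const double* t = (uidx == 0) ? ta : tb;
      double sgn = (uidx == 0) ? 1.0 : -1.0; // force on b = -fa
      double fpar_plus = sgn * (fa[0]*t[0]+fa[1]*t[1]+fa[2]*t[2]);
      E.loadPar[uidx][i] = U.motor ? fpar_plus * U.dir : fpar_plus;
    }
  }
}

// Soft-core repulsion between close segments of distinct filaments, with
// the axial components removed so that sliding is not resisted.
static void steric_forces(Eng& E, const Grid& G) {
  if (E.kSter <= 0) return;
  int ns = (int)G.segFil.size();
  int cells[9];
  for (int s1 = 0; s1 < ns; s1++) {
    int f1 = G.segFil[s1], j1 = G.segIdx[s1];
    const Fil& A = E.fils[f1];
    const double* p1 = &A.v[3 * j1];
    const double* q1 = &A.v[3 * (j1 + 1)];
    int nc = G.neighbors(G.midw[3 * s1], G.midw[3 * s1 + 1], cells);
    for (int ci = 0; ci < nc; ci++) {
      for (int s2 = G.head[cells[ci]]; s2 >= 0; s2 = G.nxt[s2]) {
        if (s2 <= s1) continue;
        int f2 = G.segFil[s2];
        if (f2 == f1) continue;
        // cheap pre-rejection on wrapped midpoint distance
        double rx = E.wrapdx(G.midw[3 * s2] - G.midw[3 * s1]);
        double ry = E.wrapdy(G.midw[3 * s2 + 1] - G.midw[3 * s1 + 1]);
        double rz = G.midw[3 * s2 + 2] - G.midw[3 * s1 + 2];
        double rr = G.halfLen[s1] + G.halfLen[s2] + E.dSter;
        if (rx * rx + ry * ry + rz * rz >= rr * rr) continue;
        int j2 = G.segIdx[s2];
        const Fil& B = E.fils[f2];
        // shift segment 2 so its midpoint sits at the minimum image of the
        // (unwrapped) midpoint offset from segment 1
        double m1x = 0.5 * (A.v[3 * j1] + A.v[3 * (j1 + 1)]);
        double m1y = 0.5 * (A.v[3 * j1 + 1] + A.v[3 * (j1 + 1) + 1]);
        double m2x = 0.5 * (B.v[3 * j2] + B.v[3 * (j2 + 1)]);
        double m2y = 0.5 * (B.v[3 * j2 + 1] + B.v[3 * (j2 + 1) + 1]);
        double shx = E.wrapdx(m2x - m1x) - (m2x - m1x);
        double shy = E.wrapdy(m2y - m1y) - (m2y - m1y);
        double p2s[3] = {B.v[3 * j2] + shx, B.v[3 * j2 + 1] + shy,
                         B.v[3 * j2 + 2]};
        double q2s[3] = {B.v[3 * (j2 + 1)] + shx, B.v[3 * (j2 + 1) + 1] + shy,
                         B.v[3 * (j2 + 1) + 2]};
        double s, t, c1[3], c2[3];
        double d2 = seg_seg(p1, q1, p2s, q2s, s, t, c1, c2);
        if (d2 >= E.dSter * E.dSter) continue;
        double r = std::sqrt(d2);
        double n[3];
        if (r > 1e-9) for (int c = 0; c < 3; c++) n[c] = (c2[c] - c1[c]) / r;
        else { // coincident: random perpendicular direction
          double th = 2.0 * M_PI * E.rng.unif();
          n[0] = std::cos(th); n[1] = std::sin(th); n[2] = 0;
        }
        double tA[3], tB[3], lA = 0, lB = 0;
        for (int c = 0; c < 3; c++) {
          tA[c] = q1[c] - p1[c]; lA += tA[c] * tA[c];
          tB[c] = q2s[c] - p2s[c]; lB += tB[c] * tB[c];
        }
        lA = std::sqrt(lA); lB = std::sqrt(lB);
        if (lA > 0) for (int c = 0; c < 3; c++) tA[c] /= lA;
        if (lB > 0) for (int c = 0; c < 3; c++) tB[c] /= lB;
        double na = n[0]*tA[0]+n[1]*tA[1]+n[2]*tA[2];
        double nb = n[0]*tB[0]+n[1]*tB[1]+n[2]*tB[2];
        double np[3];
        for (int c = 0; c < 3; c++) np[c] = n[c] - na * tA[c] - nb * tB[c];
        double nn = std::sqrt(np[0]*np[0]+np[1]*np[1]+np[2]*np[2]);
        if (nn < 1e-9 || (np[0]*n[0]+np[1]*n[1]+np[2]*n[2]) <= 0) {
          // axes nearly parallel to the gap: pick a random direction
          // perpendicular to tA
          double th = 2.0 * M_PI * E.rng.unif();
          double e1[3], e2[3];
          // orthonormal frame around tA
          double ax2 = std::fabs(tA[0]) < 0.9 ? 1.0 : 0.0;
          double ref[3] = {ax2, 1.0 - ax2, 0.0};
          e1[0] = tA[1]*ref[2]-tA[2]*ref[1];
          e1[1] = tA[2]*ref[0]-tA[0]*ref[2];
          e1[2] = tA[0]*ref[1]-tA[1]*ref[0];
          double en = std::sqrt(e1[0]*e1[0]+e1[1]*e1[1]+e1[2]*e1[2]);
          for (int c = 0; c < 3; c++) e1[c] /= en;
          e2[0] = tA[1]*e1[2]-tA[2]*e1[1];
          e2[1] = tA[2]*e1[0]-tA[0]*e1[2];
          e2[2] = tA[0]*e1[1]-tA[1]*e1[0];
          for (int c = 0; c < 3; c++)
            np[c] = std::cos(th) * e1[c] + std::sin(th) * e2[c];
          nn = 1.0;
        }
        for (int c = 0; c < 3; c++) np[c] /= nn;
        double mag = E.kSter * (E.dSter - r);
        double* FA = E.F[f1].data();
        double* FB = E.F[f2].data();
        for (int c = 0; c < 3; c++) {
          double fc = mag * np[c]; // push B away from A along +np
          FB[3 * j2 + c]       += (1.0 - t) * fc;
          FB[3 * (j2 + 1) + c] += t * fc;
          FA[3 * j1 + c]       -= (1.0 - s) * fc;
          FA[3 * (j1 + 1) + c] -= s * fc;
        }
        if (!E.Kv.empty()) {
          E.Kv[f2][j2]     += E.kSter * (1.0 - t);
          E.Kv[f2][j2 + 1] += E.kSter * t;
          E.Kv[f1][j1]     += E.kSter * (1.0 - s);
          E.Kv[f1][j1 + 1] += E.kSter * s;
        }
      }
    }
  }
}

static void bending_forces_fil(const Eng& E, const Fil& f,
                               std::vector<double>& out) {
  out.assign(3 * f.nv, 0.0);
  double c0 = E.kappa / (E.lseg * E.lseg * E.lseg);
  for (int i = 0; i + 2 < f.nv; i++) {
    for (int c = 0; c < 3; c++) {
      double g = c0 * (f.v[3*i+c] - 2.0*f.v[3*(i+1)+c] + f.v[3*(i+2)+c]);
      out[3*i+c]     -= g;
      out[3*(i+1)+c] += 2.0 * g;
      out[3*(i+2)+c] -= g;
    }
  }
}

// ----------------------------------------------------------- integration --
static void integrate_vertices(Eng& E) {
  double sfree = std::sqrt(2.0 * E.kBT * E.dt / E.gamV);
  std::vector<double> w, y;
  for (size_t fi = 0; fi < E.fils.size(); fi++) {
    Fil& f = E.fils[fi];
    const std::vector<double>& Fv = E.F[fi];
    const std::vector<double>& Kf = E.Kv[fi];
    // soft-force drift, capped at a quarter segment length per step (a
    // numerical safeguard against rare force spikes in dense clusters)
    double dcap = 0.25 * E.lseg;
    std::vector<double> drift(3 * f.nv);
    for (int i = 0; i < f.nv; i++) {
      double dg = E.dt / (E.gamV + Kf[i] * E.dt);
      double nn = 0;
      for (int c = 0; c < 3; c++) {
        drift[3 * i + c] = dg * Fv[3 * i + c];
        nn += drift[3 * i + c] * drift[3 * i + c];
      }
      nn = std::sqrt(nn);
      if (nn > dcap) {
        for (int c = 0; c < 3; c++) drift[3 * i + c] *= dcap / nn;
      }
    }
    if (f.nv == 2) {
      for (int i = 0; i < 6; i++)
        f.v[i] += drift[i] + sfree * E.rng.normal();
      continue;
    }
    ensure_ou(E, f.nv);
    const std::vector<double>& Q = E.cQ[f.nv];
    const std::vector<double>& C = E.cC[f.nv];
    const std::vector<double>& S = E.cS[f.nv];
    int n = f.nv;
    w.resize(n); y.resize(n);
    for (int c = 0; c < 3; c++) {
      for (int i = 0; i < n; i++)
        w[i] = f.v[3 * i + c] + drift[3 * i + c];
      for (int k = 0; k < n; k++) {
        double acc = 0;
        for (int i = 0; i < n; i++) acc += Q[i * n + k] * w[i];
        y[k] = C[k] * acc + S[k] * E.rng.normal();
      }
      for (int i = 0; i < n; i++) {
        double acc = 0;
        for (int k = 0; k < n; k++) acc += Q[i * n + k] * y[k];
        f.v[3 * i + c] = acc;
      }
    }
  }
}

// Newton iteration on the bond-length constraints: solve the tridiagonal
// Gram system (J J^T) lambda = -g for the Lagrange multipliers and apply
// the correction along the bond directions; quadratic convergence from the
// small post-update violations. Returns false on degenerate geometry.
static bool constrain_newton(const Eng& E, Fil& f) {
  int nseg = f.nv - 1;
  if (nseg < 1) return true;
  std::vector<double> ux(nseg), uy(nseg), uz(nseg), g(nseg),
      dia(nseg), off(nseg), lam(nseg);
  for (int iter = 0; iter < 12; iter++) {
    double maxrel = 0;
    for (int j = 0; j < nseg; j++) {
      double rest = (j == nseg - 1) ? f.last_rest : E.lseg;
      double dx = f.v[3 * (j + 1)] - f.v[3 * j];
      double dy = f.v[3 * (j + 1) + 1] - f.v[3 * j + 1];
      double dz = f.v[3 * (j + 1) + 2] - f.v[3 * j + 2];
      double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (!std::isfinite(dist) || dist < 1e-9) return false;
      ux[j] = dx / dist; uy[j] = dy / dist; uz[j] = dz / dist;
      g[j] = dist - rest;
      double rel = std::fabs(g[j]) / rest;
      if (rel > maxrel) maxrel = rel;
    }
    if (maxrel < E.tol_constraint) return true;
    for (int j = 0; j < nseg; j++) {
      dia[j] = 2.0;
      off[j] = (j + 1 < nseg)
        ? -(ux[j] * ux[j + 1] + uy[j] * uy[j + 1] + uz[j] * uz[j + 1])
        : 0.0;
      lam[j] = -g[j];
    }
    // Thomas solve (in place)
    for (int j = 1; j < nseg; j++) {
      double m = off[j - 1] / dia[j - 1];
      dia[j] -= m * off[j - 1];
      lam[j] -= m * lam[j - 1];
    }
    lam[nseg - 1] /= dia[nseg - 1];
    for (int j = nseg - 2; j >= 0; j--) {
      lam[j] = (lam[j] - off[j] * lam[j + 1]) / dia[j];
    }
    for (int i = 0; i < f.nv; i++) {
      double cx = 0, cy = 0, cz = 0;
      if (i > 0) { cx += lam[i - 1] * ux[i - 1];
                   cy += lam[i - 1] * uy[i - 1];
                   cz += lam[i - 1] * uz[i - 1]; }
      if (i < nseg) { cx -= lam[i] * ux[i];
                      cy -= lam[i] * uy[i];
                      cz -= lam[i] * uz[i]; }
      f.v[3 * i] += cx; f.v[3 * i + 1] += cy; f.v[3 * i + 2] += cz;
    }
  }
  return false;
}

static void constrain_fil(const Eng& E, Fil& f, int fil_id) {
  if (constrain_newton(E, f)) return;
  int nseg = f.nv - 1;
  double maxrel = 0;
  for (int it = 0; it < 1000; it++) {
    maxrel = 0;
    // alternate sweep direction (symmetric Gauss-Seidel)
    bool fwd = (it % 2 == 0);
    for (int jj = 0; jj < nseg; jj++) {
      int j = fwd ? jj : (nseg - 1 - jj);
      double rest = (j == nseg - 1) ? f.last_rest : E.lseg;
      double d[3], dist2 = 0;
      for (int c = 0; c < 3; c++) {
        d[c] = f.v[3 * (j + 1) + c] - f.v[3 * j + c];
        dist2 += d[c] * d[c];
      }
      double dist = std::sqrt(dist2);
      if (!std::isfinite(dist))
        stop("non-finite geometry in filament %d", fil_id + 1);
      double err = dist - rest;
      double rel = std::fabs(err) / rest;
      if (rel > maxrel) maxrel = rel;
      if (dist > 1e-12) {
        double cf = 0.5 * err / dist;
        for (int c = 0; c < 3; c++) {
          f.v[3 * j + c]       += cf * d[c];
          f.v[3 * (j + 1) + c] -= cf * d[c];
        }
      } else {
        // coincident vertices: separate along a fixed axis
        f.v[3 * j]       -= 0.5 * rest;
        f.v[3 * (j + 1)] += 0.5 * rest;
      }
    }
    if (maxrel < E.tol_constraint) return;
  }
  stop("segment-length constraint did not converge for filament %d (nv=%d, residual %g)",
       fil_id + 1, f.nv, maxrel);
}

static void reflect_all(Eng& E) {
  double L2 = 2.0 * E.Lz;
  for (size_t fi = 0; fi < E.fils.size(); fi++) {
    Fil& f = E.fils[fi];
    for (int i = 0; i < f.nv; i++) {
      double z = f.v[3 * i + 2];
      z = z - L2 * std::floor(z / L2);
      if (z > E.Lz) z = L2 - z;
      f.v[3 * i + 2] = z;
    }
  }
}

// --------------------------------------------------------------- growth ---
static void grow_and_nucleate(Eng& E) {
  if (!E.has_growth || E.time_ >= E.growthUntil) return;
  // nucleation
  double pnuc = 1.0 - std::exp(-E.nucRate * E.dt);
  for (size_t s = 0; s < E.seedUsed.size(); s++) {
    if (E.seedUsed[s]) continue;
    if (E.poly + E.initLen > E.omega) break;
    if (E.rng.unif() >= pnuc) continue;
    double th = 2.0 * M_PI * E.rng.unif();
    Fil f;
    f.nv = 2;
    f.v.resize(6);
    for (int c = 0; c < 3; c++) f.v[c] = E.seedp[3 * s + c];
    f.v[3] = f.v[0] + E.initLen * std::cos(th);
    f.v[4] = f.v[1] + E.initLen * std::sin(th);
    f.v[5] = f.v[2];
    f.last_rest = E.initLen;
    double al = E.alpha0 * std::fabs(1.0 + E.sdfac * E.rng.normal());
    f.alpha = std::min(E.clipHi, std::max(E.clipLo, al));
    E.fils.push_back(f);
    E.seedUsed[s] = 1;
    E.poly += E.initLen;
  }
  // growth: speeds from pool at step start, caps applied sequentially
  double poly0 = E.poly;
  for (size_t fi = 0; fi < E.fils.size(); fi++) {
    Fil& f = E.fils[fi];
    double vg = f.alpha * (1.0 - poly0 / E.omega);
    if (vg <= 0) continue;
    double dl = std::min(vg * E.dt, E.omega - E.poly);
    if (dl <= 0) continue;
    int n = f.nv;
    double t[3], nn = 0;
    for (int c = 0; c < 3; c++) {
      t[c] = f.v[3 * (n - 1) + c] - f.v[3 * (n - 2) + c];
      nn += t[c] * t[c];
    }
    nn = std::sqrt(nn);
    if (nn <= 0) continue;
    for (int c = 0; c < 3; c++) {
      t[c] /= nn;
      f.v[3 * (n - 1) + c] += dl * t[c];
    }
    f.last_rest += dl;
    E.poly += dl;
    if (f.last_rest > 1.5 * E.lseg) {
      double rem = f.last_rest - E.lseg;
      double nv_[3];
      for (int c = 0; c < 3; c++)
        nv_[c] = f.v[3 * (n - 2) + c] + E.lseg * t[c];
      f.v.insert(f.v.begin() + 3 * (n - 1), nv_, nv_ + 3);
      f.nv++;
      f.last_rest = rem;
    }
  }
}

// -------------------------------------------------------------- kinetics --
static void unbind_to_free(Eng& E, Lnk& L, int uidx) {
  if (L.fil[1 - uidx] < 0) {
    // partner also unbound: park complex at the released anchor
    double p[3], t[3], w; int j;
    anchor_geom(E, E.fils[L.fil[uidx]], L.absc[uidx], p, j, w, t);
    for (int c = 0; c < 3; c++) L.pos[c] = p[c];
    L.diff_accum = 0;
  }
  L.fil[uidx] = -1;
  L.absc[uidx] = 0;
  L.try_in[uidx] = E.rng.geom(E.types[L.type].u[uidx].pbind);
}

// apply the accumulated free diffusion of a fully unbound complex as one
// Gaussian jump (the exact marginal of the per-step process), then wrap and
// reflect
static void flush_diffusion(Eng& E, Lnk& L) {
  if (L.diff_accum <= 0) return;
  double s = std::sqrt(2.0 * E.kBT * E.dt * L.diff_accum / E.gamL);
  for (int c = 0; c < 3; c++) L.pos[c] += s * E.rng.normal();
  L.pos[0] -= E.Lx * std::floor(L.pos[0] / E.Lx);
  L.pos[1] -= E.Ly * std::floor(L.pos[1] / E.Ly);
  double L2 = 2.0 * E.Lz;
  double z = L.pos[2] - L2 * std::floor(L.pos[2] / L2);
  if (z > E.Lz) z = L2 - z;
  L.pos[2] = z;
  L.diff_accum = 0;
}

static void linker_kinetics(Eng& E, const Grid& G) {
  double a = SITE;
  int cells[9];
  std::vector<std::pair<int, double> > cand; // (filament, abscissa)
  for (size_t i = 0; i < E.lnks.size(); i++) {
    Lnk& L = E.lnks[i];
    const LType& T = E.types[L.type];
    // 1) unbinding (Bell law on the recorded spring load magnitude),
    //    plus instant release for end-released units sitting at their end
    for (int u = 0; u < 2; u++) {
      if (L.fil[u] < 0) continue;
      const Unit& U = T.u[u];
      double len = E.fils[L.fil[u]].length(E.lseg);
      if (U.release) {
        bool at_end = U.motor
          ? std::fabs(L.absc[u] - (U.dir > 0 ? len : 0.0)) < 1e-9
          : (L.absc[u] <= 1e-9 || L.absc[u] >= len - 1e-9);
        if (at_end) { unbind_to_free(E, L, u); continue; }
      }
      double poff;
      if (E.loadMag[i] == 0.0) {
        poff = U.poff0;
      } else {
        double y = E.loadMag[i] / U.funb;
        double bell = (y < 0.01) ? 1.0 + y * (1.0 + 0.5 * y) : std::exp(y);
        double x = U.koff0 * bell * E.dt;
        poff = (x < 1e-3) ? x * (1.0 - 0.5 * x) : 1.0 - std::exp(-x);
      }
      if (poff > 0 && E.rng.unif() < poff) unbind_to_free(E, L, u);
    }
    // 2) movement of bound units (loads recorded before the vertex update)
    for (int u = 0; u < 2; u++) {
      if (L.fil[u] < 0) continue;
      const Unit& U = T.u[u];
      double len = E.fils[L.fil[u]].length(E.lseg);
      double fpar = (L.fil[1 - u] >= 0) ? E.loadPar[u][i] : 0.0;
      if (U.motor) {
        if (U.vm <= 0) continue;
        int nst;
        if (fpar == 0.0) {
          nst = E.rng.poissonL(U.L_step0);
        } else {
          double v = U.vm * (1.0 + fpar / U.fs);
          if (v < 0) v = 0;
          if (v > 2.0 * U.vm) v = 2.0 * U.vm;
          nst = (v > 0) ? E.rng.poisson(v / a * E.dt) : 0;
        }
        if (nst == 0) continue;
        double target = L.absc[u] + U.dir * nst * a;
        double endp = U.dir > 0 ? len : 0.0;
        bool past = U.dir > 0 ? (target >= len) : (target <= 0.0);
        if (past) {
          if (U.release) unbind_to_free(E, L, u);
          else L.absc[u] = endp;
        } else {
          L.absc[u] = target;
        }
      } else {
        if (U.D <= 0) continue;
        // net hop count over dt: Skellam(mup, mum), Gaussian limit when the
        // event count is large (strong bias); ends clamp or release
        long net;
        if (fpar == 0.0) {
          net = E.rng.poissonL(U.L_hop0) - E.rng.poissonL(U.L_hop0);
        } else {
          double b = fpar * a / (2.0 * E.kBT);
          if (b > 30) b = 30; if (b < -30) b = -30;
          double eb = std::exp(b);
          double mup = U.r0 * eb * E.dt, mum = U.r0 / eb * E.dt;
          if (mup + mum > 500.0) {
            net = std::lround((mup - mum) +
                              std::sqrt(mup + mum) * E.rng.normal());
          } else {
            net = E.rng.poisson(mup) - E.rng.poisson(mum);
          }
        }
        if (net != 0) {
          double na_ = L.absc[u] + net * a;
          if (na_ < 0.0 || na_ > len) {
            if (U.release) unbind_to_free(E, L, u);
            else L.absc[u] = (na_ < 0.0) ? 0.0 : len;
          } else {
            L.absc[u] = na_;
          }
        }
      }
    }
    // 3) binding attempts of unbound units (exact geometric event skip)
    for (int u = 0; u < 2; u++) {
      if (L.fil[u] >= 0) continue;
      const Unit& U = T.u[u];
      if (U.pbind <= 0) continue;
      if (--L.try_in[u] > 0) continue;
      L.try_in[u] = E.rng.geom(U.pbind);
      if (L.fil[1 - u] < 0) flush_diffusion(E, L);
      double sp[3];
      int exclude = -1;
      if (L.fil[1 - u] >= 0) {
        double t[3], w; int j;
        anchor_geom(E, E.fils[L.fil[1 - u]], L.absc[1 - u], sp, j, w, t);
        exclude = L.fil[1 - u];
      } else {
        for (int c = 0; c < 3; c++) sp[c] = L.pos[c];
      }
      double wx = sp[0] - E.Lx * std::floor(sp[0] / E.Lx);
      double wy = sp[1] - E.Ly * std::floor(sp[1] / E.Ly);
      int nc = G.neighbors(wx, wy, cells);
      cand.clear();
      for (int ci = 0; ci < nc; ci++) {
        for (int s = G.head[cells[ci]]; s >= 0; s = G.nxt[s]) {
          int fidx = G.segFil[s];
          if (fidx == exclude) continue;
          const Fil& f = E.fils[fidx];
          int j = G.segIdx[s];
          // segment shifted by minimum image relative to the search point
          double mx = 0.5 * (f.v[3 * j] + f.v[3 * (j + 1)]);
          double my = 0.5 * (f.v[3 * j + 1] + f.v[3 * (j + 1) + 1]);
          double shx = E.wrapdx(mx - sp[0]) - (mx - sp[0]);
          double shy = E.wrapdy(my - sp[1]) - (my - sp[1]);
          double v0[3] = {f.v[3 * j] + shx, f.v[3 * j + 1] + shy,
                          f.v[3 * j + 2]};
          double dseg[3] = {f.v[3 * (j + 1)] - f.v[3 * j],
                            f.v[3 * (j + 1) + 1] - f.v[3 * j + 1],
                            f.v[3 * (j + 1) + 2] - f.v[3 * j + 2]};
          double m[3] = {v0[0] - sp[0], v0[1] - sp[1], v0[2] - sp[2]};
          double A = dseg[0]*dseg[0]+dseg[1]*dseg[1]+dseg[2]*dseg[2];
          double Bq = m[0]*dseg[0]+m[1]*dseg[1]+m[2]*dseg[2];
          double Cq = m[0]*m[0]+m[1]*m[1]+m[2]*m[2] - U.range * U.range;
          if (A <= 1e-18) continue;
          double disc = Bq * Bq - A * Cq;
          if (disc <= 0) continue;
          double sq = std::sqrt(disc);
          double slo = std::max(0.0, (-Bq - sq) / A);
          double shi = std::min(1.0, (-Bq + sq) / A);
          if (shi <= slo) continue;
          int nseg = f.nv - 1;
          double rest = (j == nseg - 1) ? f.last_rest : E.lseg;
          double alo = j * E.lseg + slo * rest;
          double ahi = j * E.lseg + shi * rest;
          double len = f.length(E.lseg);
          int ilo = (int)std::ceil(alo / a - 0.5);
          int ihi = (int)std::floor(ahi / a - 0.5);
          if (ilo < 0) ilo = 0;
          for (int is = ilo; is <= ihi; is++) {
            double absc = (is + 0.5) * a;
            if (absc > len) break;
            cand.push_back(std::make_pair(fidx, absc));
          }
        }
      }
      if (cand.empty()) continue;
      int pick = (int)(E.rng.unif() * cand.size());
      if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
      L.fil[u] = cand[pick].first;
      L.absc[u] = cand[pick].second;
    }
    // 4) free diffusion of fully unbound complexes: accumulated here,
    // applied as one exact Gaussian jump at the next binding attempt (or at
    // the end of the run)
    if (L.fil[0] < 0 && L.fil[1] < 0) L.diff_accum++;
  }
}

// ------------------------------------------------------- state marshaling --
static Eng parse_state(List st) {
  Eng E;
  NumericVector box = st["box"];
  E.Lx = box[0]; E.Ly = box[1]; E.Lz = box[2];
  E.time_ = as<double>(st["time"]);
  List ph = st["physics"];
  E.dt = as<double>(ph["dt"]);
  E.kBT = as<double>(ph["kBT"]);
  E.gamV = as<double>(ph["gamma_vertex"]);
  E.gamL = as<double>(ph["gamma_linker"]);
  E.kSter = as<double>(ph["k_steric"]);
  E.dSter = as<double>(ph["d_steric"]);
  E.kappa = as<double>(ph["rigidity"]);
  E.lseg = as<double>(ph["rest_segment_length"]);
  E.tol_constraint = 1e-6;
  List pool = st["pool"];
  E.omega = as<double>(pool["omega"]);
  E.poly = as<double>(pool["polymerized"]);
  E.has_growth = !Rf_isNull(st["growth"]);
  E.alpha0 = 0; E.sdfac = 0; E.clipLo = 0; E.clipHi = 2;
  E.nucRate = 0; E.growthUntil = -1; E.initLen = 0.1;
  if (E.has_growth) {
    List g = st["growth"];
    E.alpha0 = as<double>(g["alpha0"]);
    E.sdfac = as<double>(g["speed_sd_factor"]);
    NumericVector cl = g["speed_clip"];
    E.clipLo = cl[0]; E.clipHi = cl[1];
    E.nucRate = as<double>(g["nucleation_rate"]);
    E.growthUntil = as<double>(g["growth_until"]);
    E.initLen = as<double>(g["initial_length"]);
  }
  if (!Rf_isNull(st["seeds"])) {
    List sd = st["seeds"];
    NumericMatrix sp = sd["pos"];
    LogicalVector su = sd["used"];
    for (int i = 0; i < sp.nrow(); i++) {
      E.seedp.push_back(sp(i, 0));
      E.seedp.push_back(sp(i, 1));
      E.seedp.push_back(sp(i, 2));
      E.seedUsed.push_back(su[i] ? 1 : 0);
    }
  }
  List fl = st["fil"];
  IntegerVector nv = fl["nv"];
  NumericMatrix V = fl["vertices"];
  NumericVector alpha = fl["alpha"];
  NumericVector lr = fl["last_rest"];
  int off = 0;
  for (int i = 0; i < nv.size(); i++) {
    Fil f;
    f.nv = nv[i];
    f.alpha = alpha[i];
    f.last_rest = lr[i];
    f.v.resize(3 * f.nv);
    for (int k = 0; k < f.nv; k++)
      for (int c = 0; c < 3; c++)
        f.v[3 * k + c] = V(off + k, c);
    off += f.nv;
    E.fils.push_back(f);
  }
  List lt = st["linker_types"];
  for (int t = 0; t < lt.size(); t++) {
    List sp = lt[t];
    LType T;
    T.k = as<double>(sp["k_spring"]);
    T.e = as<double>(sp["rest_length"]);
    List us[2] = {sp["unit_a"], sp["unit_b"]};
    for (int u = 0; u < 2; u++) {
      std::string kind = as<std::string>(us[u]["kind"]);
      std::string dir = as<std::string>(us[u]["direction"]);
      std::string ep = as<std::string>(us[u]["end_policy"]);
      T.u[u].motor = (kind == "motor");
      T.u[u].dir = (dir == "toward_plus") ? 1.0 : -1.0;
      T.u[u].vm = as<double>(us[u]["vm"]);
      T.u[u].fs = as<double>(us[u]["fs"]);
      T.u[u].D = as<double>(us[u]["D"]);
      T.u[u].kon = as<double>(us[u]["k_on"]);
      T.u[u].range = as<double>(us[u]["binding_range"]);
      T.u[u].koff0 = as<double>(us[u]["k_off0"]);
      T.u[u].funb = as<double>(us[u]["f_unb"]);
      T.u[u].release = (ep == "release");
      T.u[u].pbind = 1.0 - std::exp(-T.u[u].kon * E.dt);
      T.u[u].poff0 = 1.0 - std::exp(-T.u[u].koff0 * E.dt);
      T.u[u].r0 = T.u[u].D / (SITE * SITE);
      T.u[u].L_hop0 = std::exp(-T.u[u].r0 * E.dt);
      T.u[u].L_step0 = std::exp(-T.u[u].vm / SITE * E.dt);
    }
    E.types.push_back(T);
  }
  if (!Rf_isNull(st["linkers"])) {
    List lk = st["linkers"];
    IntegerVector ty = lk["type"];
    IntegerMatrix lf = lk["fil"];
    NumericMatrix la = lk["absc"];
    NumericMatrix lp = lk["pos"];
    for (int i = 0; i < ty.size(); i++) {
      Lnk L;
      L.type = ty[i] - 1;
      for (int u = 0; u < 2; u++) {
        L.fil[u] = lf(i, u) - 1; // 0 -> -1 unbound
        L.absc[u] = la(i, u);
      }
      for (int c = 0; c < 3; c++) L.pos[c] = lp(i, c);
      E.lnks.push_back(L);
    }
  }
  // RNG state
  if (!Rf_isNull(st["rng"])) {
    RawVector rw = st["rng"];
    std::memcpy(E.rng.s, RAW(rw), 32);
  } else {
    E.rng.seed((uint64_t)as<double>(st["seed"]));
  }
  // event-skip counters (memoryless, resampled per run)
  for (size_t i = 0; i < E.lnks.size(); i++) {
    E.lnks[i].diff_accum = 0;
    for (int u = 0; u < 2; u++) {
      E.lnks[i].try_in[u] = (E.lnks[i].fil[u] < 0)
        ? E.rng.geom(E.types[E.lnks[i].type].u[u].pbind) : 0;
    }
  }
  return E;
}

static List dump_state(const Eng& E, List proto) {
  List st = clone(proto);
  st["time"] = E.time_;
  st["pool"] = List::create(_["omega"] = E.omega,
                            _["polymerized"] = E.poly);
  int ntot = 0;
  for (size_t i = 0; i < E.fils.size(); i++) ntot += E.fils[i].nv;
  NumericMatrix V(ntot, 3);
  IntegerVector nv(E.fils.size());
  NumericVector alpha(E.fils.size()), lr(E.fils.size()), len(E.fils.size());
  int off = 0;
  for (size_t i = 0; i < E.fils.size(); i++) {
    const Fil& f = E.fils[i];
    nv[i] = f.nv; alpha[i] = f.alpha; lr[i] = f.last_rest;
    len[i] = f.length(E.lseg);
    for (int k = 0; k < f.nv; k++)
      for (int c = 0; c < 3; c++) V(off + k, c) = f.v[3 * k + c];
    off += f.nv;
  }
  st["fil"] = List::create(_["nv"] = nv, _["vertices"] = V,
                           _["alpha"] = alpha, _["last_rest"] = lr,
                           _["length"] = len);
  if (!E.seedUsed.empty()) {
    List sd = st["seeds"];
    LogicalVector su(E.seedUsed.size());
    for (size_t i = 0; i < E.seedUsed.size(); i++) su[i] = E.seedUsed[i] != 0;
    sd["used"] = su;
    st["seeds"] = sd;
  }
  if (!E.lnks.empty()) {
    int n = (int)E.lnks.size();
    IntegerVector ty(n);
    IntegerMatrix lf(n, 2);
    NumericMatrix la(n, 2), lp(n, 3);
    for (int i = 0; i < n; i++) {
      ty[i] = E.lnks[i].type + 1;
      for (int u = 0; u < 2; u++) {
        lf(i, u) = E.lnks[i].fil[u] + 1;
        la(i, u) = E.lnks[i].absc[u];
      }
      for (int c = 0; c < 3; c++) lp(i, c) = E.lnks[i].pos[c];
    }
    st["linkers"] = List::create(_["type"] = ty, _["fil"] = lf,
                                 _["absc"] = la, _["pos"] = lp);
  }
  RawVector rw(32);
  std::memcpy(RAW(rw), E.rng.s, 32);
  st["rng"] = rw;
  return st;
}

static List capture_frame(const Eng& E) {
  int ntot = 0;
  for (size_t i = 0; i < E.fils.size(); i++) ntot += E.fils[i].nv;
  NumericMatrix V(ntot, 3);
  IntegerVector nv(E.fils.size());
  NumericVector len(E.fils.size());
  int off = 0;
  double tot = 0;
  for (size_t i = 0; i < E.fils.size(); i++) {
    const Fil& f = E.fils[i];
    nv[i] = f.nv;
    len[i] = f.length(E.lseg);
    tot += len[i];
    for (int k = 0; k < f.nv; k++)
      for (int c = 0; c < 3; c++) V(off + k, c) = f.v[3 * k + c];
    off += f.nv;
  }
  int n = (int)E.lnks.size();
  IntegerVector ty(n), fa(n), fb(n);
  NumericVector aa(n), ab(n);
  for (int i = 0; i < n; i++) {
    ty[i] = E.lnks[i].type + 1;
    fa[i] = E.lnks[i].fil[0] + 1;
    fb[i] = E.lnks[i].fil[1] + 1;
    aa[i] = E.lnks[i].absc[0];
    ab[i] = E.lnks[i].absc[1];
  }
  return List::create(
    _["time"] = E.time_,
    _["nv"] = nv,
    _["vertices"] = V,
    _["length"] = len,
    _["linkers"] = List::create(_["type"] = ty, _["fil_a"] = fa,
                                _["fil_b"] = fb, _["absc_a"] = aa,
                                _["absc_b"] = ab),
    _["polymerized"] = E.poly,
    _["total_length"] = tot);
}

static void one_step(Eng& E, Grid& G) {
  { PhaseTimer pt(0);
    grow_and_nucleate(E);
    E.F.resize(E.fils.size());
    E.Kv.resize(E.fils.size());
    for (size_t i = 0; i < E.fils.size(); i++) {
      E.F[i].assign(3 * E.fils[i].nv, 0.0);
      E.Kv[i].assign(E.fils[i].nv, 0.0);
    }
  }
  { PhaseTimer pt(1);
    double maxrange = 0;
    for (size_t t = 0; t < E.types.size(); t++)
      for (int u = 0; u < 2; u++)
        maxrange = std::max(maxrange, E.types[t].u[u].range);
    double cell = std::max(E.dSter + 1.5 * E.lseg,
                           maxrange + 0.85 * E.lseg);
    G.build(E, cell);
  }
  { PhaseTimer pt(2); spring_forces(E); }
  { PhaseTimer pt(3); steric_forces(E, G); }
  { PhaseTimer pt(4); integrate_vertices(E); }
  { PhaseTimer pt(5);
    for (size_t i = 0; i < E.fils.size(); i++)
      constrain_fil(E, E.fils[i], (int)i);
    reflect_all(E);
  }
  { PhaseTimer pt(6); linker_kinetics(E, G); }
  E.time_ += E.dt;
}

// [[Rcpp::export]]
List engine_run(List state, int n_steps, int stride, bool record) {
  Eng E = parse_state(state);
  Grid G;
  List frames;
  std::vector<List> fr;
  if (record) fr.push_back(capture_frame(E));
  for (int s = 1; s <= n_steps; s++) {
    one_step(E, G);
    if (record && stride > 0 && s % stride == 0)
      fr.push_back(capture_frame(E));
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  // flush pending free diffusion so the dumped state is current
  for (size_t i = 0; i < E.lnks.size(); i++) {
    if (E.lnks[i].fil[0] < 0 && E.lnks[i].fil[1] < 0)
      flush_diffusion(E, E.lnks[i]);
  }
  List out_frames(fr.size());
  for (size_t i = 0; i < fr.size(); i++) out_frames[i] = fr[i];
  NumericVector tim(8);
  for (int i = 0; i < 8; i++) { tim[i] = g_time[i]; g_time[i] = 0; }
  tim.names() = CharacterVector::create("growth", "grid", "spring", "steric",
                                        "integrate", "constrain", "kinetics",
                                        "unused");
  return List::create(_["state"] = dump_state(E, state),
                      _["frames"] = out_frames,
                      _["timing"] = tim);
}

// Force assembly diagnostic: per-vertex forces by component, plus recorded
// per-unit loads. Bending is included explicitly here (the integrator
// treats it separately, in mode space).
// [[Rcpp::export]]
List engine_forces(List state) {
  Eng E = parse_state(state);
  Grid G;
  E.F.resize(E.fils.size());
  int ntot = 0;
  for (size_t i = 0; i < E.fils.size(); i++) {
    E.F[i].assign(3 * E.fils[i].nv, 0.0);
    ntot += E.fils[i].nv;
  }
  double maxrange = 0.05;
  double cell = std::max(E.dSter + 1.5 * E.lseg, maxrange + 0.85 * E.lseg);
  G.build(E, cell);
  spring_forces(E);
  NumericMatrix Fspring(ntot, 3), Fsteric(ntot, 3), Fbend(ntot, 3);
  int off = 0;
  for (size_t i = 0; i < E.fils.size(); i++) {
    for (int k = 0; k < E.fils[i].nv; k++)
      for (int c = 0; c < 3; c++) Fspring(off + k, c) = E.F[i][3 * k + c];
    E.F[i].assign(3 * E.fils[i].nv, 0.0);
    off += E.fils[i].nv;
  }
  steric_forces(E, G);
  off = 0;
  std::vector<double> bf;
  for (size_t i = 0; i < E.fils.size(); i++) {
    bending_forces_fil(E, E.fils[i], bf);
    for (int k = 0; k < E.fils[i].nv; k++)
      for (int c = 0; c < 3; c++) {
        Fsteric(off + k, c) = E.F[i][3 * k + c];
        Fbend(off + k, c) = bf[3 * k + c];
      }
    off += E.fils[i].nv;
  }
  int n = (int)E.lnks.size();
  NumericMatrix lpar(n, 2);
  NumericVector lmag(n);
  for (int i = 0; i < n; i++) {
    lpar(i, 0) = E.loadPar[0][i];
    lpar(i, 1) = E.loadPar[1][i];
    lmag[i] = E.loadMag[i];
  }
  return List::create(_["spring"] = Fspring, _["steric"] = Fsteric,
                      _["bending"] = Fbend, _["load_par"] = lpar,
                      _["load_mag"] = lmag);
}
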