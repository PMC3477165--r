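// Core numerics for the MM/CG simulator: energy terms and analytic forces,
// level-set wall evaluation, SHAKE, and the stochastic-dynamics loop.
// Units: nm, ps, kJ/mol, amu; kB in kJ/mol/K; Coulomb factor in kJ mol-1 nm e-2.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double KB = 0.008314462618;      // kJ mol-1 K-1
static const double FELEC = 138.935458;       // kJ mol-1 nm e-2
static const double INF = std::numeric_limits<double>::infinity();

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

static inline Vec3 getv(const NumericMatrix& m, int i) {
  return Vec3(m(i, 0), m(i, 1), m(i, 2));
}
static inline void addv(NumericMatrix& m, int i, const Vec3& v) {
  m(i, 0) += v.x; m(i, 1) += v.y; m(i, 2) += v.z;
}

// ---------------------------------------------------------------------------
// Go-model terms
// ---------------------------------------------------------------------------

// Harmonic bonded term between consecutive beads: (K/2)(r - b)^2.
// [[Rcpp::export]]
List cpp_go_bonded(const NumericMatrix& pos, const IntegerMatrix& pairs,
                   const NumericVector& kb, const NumericVector& b0) {
  int n = pos.nrow(), m = pairs.nrow();
  NumericMatrix f(n, 3);
  double e = 0.0;
  for (int p = 0; p < m; ++p) {
    int i = pairs(p, 0), j = pairs(p, 1);
    Vec3 d = getv(pos, i) - getv(pos, j);
    double r = d.norm();
    if (r <= 0)
      stop("go_bonded: coincident beads in pair %d (atoms %d, %d)", p + 1, i + 1, j + 1);
    double dr = r - b0[p];
    e += 0.5 * kb[p] * dr * dr;
    double fm = -kb[p] * dr / r;   // dE/dr projected on unit vector
    Vec3 fv = d * fm;
    addv(f, i, fv);
    addv(f, j, fv * -1.0);
  }
  return List::create(_["energy"] = e, _["forces"] = f);
}

// Morse-type native contact: V(r) = V0 * ((1 - exp(-B (r - b)))^2 - 1).
// V(b) = -V0 (well depth), V(inf) -> 0.
// [[Rcpp::export]]
List cpp_go_morse(const NumericMatrix& pos, const IntegerMatrix& pairs,
                  const NumericVector& b0, const NumericVector& B,
                  const NumericVector& v0) {
  int n = pos.nrow(), m = pairs.nrow();
  NumericMatrix f(n, 3);
  double e = 0.0;
  for (int p = 0; p < m; ++p) {
    int i = pairs(p, 0), j = pairs(p, 1);
    Vec3 d = getv(pos, i) - getv(pos, j);
    double r = d.norm();
    if (r <= 0)
      stop("go_morse: coincident beads in pair %d (atoms %d, %d)", p + 1, i + 1, j + 1);
    double ex = std::exp(-B[p] * (r - b0[p]));
    double om = 1.0 - ex;
    e += v0[p] * (om * om - 1.0);
    // dV/dr = 2 V0 B (1 - ex) ex
    double dvdr = 2.0 * v0[p] * B[p] * om * ex;
    double fm = -dvdr / r;
    Vec3 fv = d * fm;
    addv(f, i, fv);
    addv(f, j, fv * -1.0);
  }
  return List::create(_["energy"] = e, _["forces"] = f);
}

// ---------------------------------------------------------------------------
// Atomistic bonded terms (harmonic bonds + angles, periodic dihedrals)
// energies split by region group of the participating atoms:
//   all group 0 -> e_mm; all group 1 -> e_i; mixed -> e_mmi
// ---------------------------------------------------------------------------
static inline void esplit(double e, int gmin, int gmax, double& emm, double& ei,
                          double& emmi) {
  if (gmin == 0 && gmax == 0) emm += e;
  else if (gmin == 1 && gmax == 1) ei += e;
  else emmi += e;
}

// [[Rcpp::export]]
List cpp_mm_bonded(const NumericMatrix& pos,
                   const IntegerMatrix& bp, const NumericVector& bk, const NumericVector& br0,
                   const IntegerMatrix& at, const NumericVector& ak, const NumericVector& ath0,
                   const IntegerMatrix& dq, const NumericVector& dk,
                   const IntegerVector& dn, const NumericVector& dph,
                   const IntegerVector& group) {
  int n = pos.nrow();
  NumericMatrix f(n, 3);
  double emm = 0, ei = 0, emmi = 0;

  for (int p = 0; p < bp.nrow(); ++p) {
    int i = bp(p, 0), j = bp(p, 1);
    Vec3 d = getv(pos, i) - getv(pos, j);
    double r = d.norm();
    if (r <= 0) stop("mm_bonded: zero-length bond %d", p + 1);
    double dr = r - br0[p];
    double e = 0.5 * bk[p] * dr * dr;
    esplit(e, std::min(group[i], group[j]), std::max(group[i], group[j]), emm, ei, emmi);
    Vec3 fv = d * (-bk[p] * dr / r);
    addv(f, i, fv);
    addv(f, j, fv * -1.0);
  }

  for (int p = 0; p < at.nrow(); ++p) {
    int i = at(p, 0), j = at(p, 1), k = at(p, 2);
    Vec3 rij = getv(pos, i) - getv(pos, j);
    Vec3 rkj = getv(pos, k) - getv(pos, j);
    double nij = rij.norm(), nkj = rkj.norm();
    if (nij <= 0 || nkj <= 0) stop("mm_bonded: degenerate angle %d", p + 1);
    double ct = rij.dot(rkj) / (nij * nkj);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
    double dth = th - ath0[p];
    double e = 0.5 * ak[p] * dth * dth;
    int gmin = std::min(group[i], std::min(group[j], group[k]));
    int gmax = std::max(group[i], std::max(group[j], group[k]));
    esplit(e, gmin, gmax, emm, ei, emmi);
    double dEdth = ak[p] * dth;
    Vec3 u = rij * (1.0 / nij), v = rkj * (1.0 / nkj);
    Vec3 fi = (v - u * ct) * (dEdth / (st * nij));
    Vec3 fk = (u - v * ct) * (dEdth / (st * nkj));
    addv(f, i, fi);
    addv(f, k, fk);
    addv(f, j, (fi + fk) * -1.0);
  }

  for (int p = 0; p < dq.nrow(); ++p) {
    int i = dq(p, 0), j = dq(p, 1), k = dq(p, 2), l = dq(p, 3);
    Vec3 b1 = getv(pos, j) - getv(pos, i);
    Vec3 b2 = getv(pos, k) - getv(pos, j);
    Vec3 b3 = getv(pos, l) - getv(pos, k);
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    double n1sq = n1.dot(n1), n2sq = n2.dot(n2);
    double b2n = b2.norm();
    if (n1sq < 1e-16 || n2sq < 1e-16 || b2n < 1e-12)
      stop("mm_bonded: degenerate dihedral %d", p + 1);
    double phi = std::atan2(n1.cross(n2).dot(b2) / b2n, n1.dot(n2));
    double e = dk[p] * (1.0 + std::cos(dn[p] * phi - dph[p]));
    int gmin = std::min(std::min(group[i], group[j]), std::min(group[k], group[l]));
    int gmax = std::max(std::max(group[i], group[j]), std::max(group[k], group[l]));
    esplit(e, gmin, gmax, emm, ei, emmi);
    double dEdphi = -dk[p] * dn[p] * std::sin(dn[p] * phi - dph[p]);
    // gradients of phi (standard torsion force decomposition)
    Vec3 gi = n1 * (-b2n / n1sq);
    Vec3 gl = n2 * (b2n / n2sq);
    double fg = b1.dot(b2), hg = b3.dot(b2), b2sq = b2n * b2n;
    Vec3 gj = gi * (-fg / b2sq - 1.0) + gl * (hg / b2sq);
    Vec3 gk = (gi + gj + gl) * -1.0;
    addv(f, i, gi * -dEdphi);
    addv(f, j, gj * -dEdphi);
    addv(f, k, gk * -dEdphi);
    addv(f, l, gl * -dEdphi);
  }

  return List::create(_["e_mm"] = emm, _["e_i"] = ei, _["e_mmi"] = emmi,
                      _["forces"] = f);
}

// ---------------------------------------------------------------------------
// Nonbonded: LJ 12-6 + Coulomb, plain cutoff with energy shift so V(rc) = 0
// ---------------------------------------------------------------------------
static inline Vec3 minimg(Vec3 d, bool pbc, const double* box) {
  if (pbc) {
    d.x -= box[0] * std::round(d.x / box[0]);
    d.y -= box[1] * std::round(d.y / box[1]);
    d.z -= box[2] * std::round(d.z / box[2]);
  }
  return d;
}

// [[Rcpp::export]]
List cpp_nonbonded(const NumericMatrix& pos, const IntegerMatrix& pairs,
                   const NumericVector& sigma, const NumericVector& eps,
                   const NumericVector& q, double cutoff,
                   const IntegerVector& group, bool pbc,
                   const NumericVector& box) {
  int n = pos.nrow(), m = pairs.nrow();
  NumericMatrix f(n, 3);
  double emm = 0, ei = 0, emmi = 0;
  double rc2 = cutoff * cutoff;
  double bx[3] = {0, 0, 0};
  if (pbc) { bx[0] = box[0]; bx[1] = box[1]; bx[2] = box[2]; }
  for (int p = 0; p < m; ++p) {
    int i = pairs(p, 0), j = pairs(p, 1);
    Vec3 d = minimg(getv(pos, i) - getv(pos, j), pbc, bx);
    double r2 = d.dot(d);
    if (r2 >= rc2) continue;
    double r = std::sqrt(r2);
    if (r < 1e-4)
      stop("nonbonded: overlapping atoms %d and %d (r = %g nm)", i + 1, j + 1, r);
    double e = 0.0, dvdr = 0.0;
    double eij = std::sqrt(eps[i] * eps[j]);
    if (eij > 0) {
      double sij = 0.5 * (sigma[i] + sigma[j]);
      double sr6 = std::pow(sij / r, 6), sc6 = std::pow(sij / cutoff, 6);
      e += 4.0 * eij * ((sr6 * sr6 - sr6) - (sc6 * sc6 - sc6));
      dvdr += 4.0 * eij * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
    }
    double qq = q[i] * q[j];
    if (qq != 0) {
      e += FELEC * qq * (1.0 / r - 1.0 / cutoff);
      dvdr += -FELEC * qq / r2;
    }
    esplit(e, std::min(group[i], group[j]), std::max(group[i], group[j]), emm, ei, emmi);
    Vec3 fv = d * (-dvdr / r);
    addv(f, i, fv);
    addv(f, j, fv * -1.0);
  }
  return List::create(_["e_mm"] = emm, _["e_i"] = ei, _["e_mmi"] = emmi,
                      _["forces"] = f);
}

// Verlet pair list over the atomistic atoms: all pairs with r < cutoff,
// excluding pairs in the exclusion table. O(N^2) build.
// [[Rcpp::export]]
IntegerMatrix cpp_build_pairs(const NumericMatrix& pos, const IntegerVector& idx,
                              double cutoff, const IntegerVector& excl_i,
                              const IntegerVector& excl_j, bool pbc,
                              const NumericVector& box) {
  int na = idx.size();
  double rc2 = cutoff * cutoff;
  double bx[3] = {0, 0, 0};
  if (pbc) { bx[0] = box[0]; bx[1] = box[1]; bx[2] = box[2]; }
  // exclusion lookup: set of keys i * N + j (i < j)
  std::vector<long long> excl;
  excl.reserve(excl_i.size());
  long long N = pos.nrow();
  for (int k = 0; k < excl_i.size(); ++k) {
    long long a = excl_i[k], b = excl_j[k];
    if (a > b) std::swap(a, b);
    excl.push_back(a * N + b);
  }
  std::sort(excl.begin(), excl.end());
  std::vector<int> out;
  for (int a = 0; a < na; ++a) {
    int i = idx[a];
    Vec3 pi = getv(pos, i);
    for (int b = a + 1; b < na; ++b) {
      int j = idx[b];
      Vec3 d = minimg(pi - getv(pos, j), pbc, bx);
      if (d.dot(d) >= rc2) continue;
      long long lo = std::min(i, j), hi = std::max(i, j);
      long long key = lo * N + hi;
      if (std::binary_search(excl.begin(), excl.end(), key)) continue;
      out.push_back(i);
      out.push_back(j);
    }
  }
  int m = out.size() / 2;
  IntegerMatrix pm(m, 2);
  for (int p = 0; p < m; ++p) { pm(p, 0) = out[2 * p]; pm(p, 1) = out[2 * p + 1]; }
  return pm;
}

// ---------------------------------------------------------------------------
// Level-set walls
// ---------------------------------------------------------------------------
struct WallPar {
  int active[5];
  double z_lo, z_hi;
  double chi3[3], chi4[3], r3, r4;
  NumericMatrix cj;       // membrane-wall source points (initial C-alpha)
  double beta, r_p, eps, sigma_rep, d_rep, sigma_p, delta, cut345, fmax, d_floor;
  double e_shift_rep, f_shift_rep, e_shift_att, f_shift_att;
  // cap onset distances of the shifted force and the force-consistent
  // potential value there (dynamics bookkeeping; see wall_Vdyn)
  double d_cap_rep, d_cap_att, v_cap_rep, v_cap_att;
};

static WallPar parse_wall(const List& w) {
  WallPar wp;
  IntegerVector act = w["active"];
  for (int i = 0; i < 5; ++i) wp.active[i] = act[i];
  wp.z_lo = as<double>(w["z_lo"]);
  wp.z_hi = as<double>(w["z_hi"]);
  NumericVector c3 = w["chi3"], c4 = w["chi4"];
  for (int i = 0; i < 3; ++i) { wp.chi3[i] = c3[i]; wp.chi4[i] = c4[i]; }
  wp.r3 = as<double>(w["r3"]);
  wp.r4 = as<double>(w["r4"]);
  wp.cj = as<NumericMatrix>(w["cj"]);
  wp.beta = as<double>(w["beta"]);
  wp.r_p = as<double>(w["r_p"]);
  wp.eps = as<double>(w["eps"]);
  wp.sigma_rep = as<double>(w["sigma"]);
  wp.d_rep = as<double>(w["d_rep"]);
  wp.sigma_p = as<double>(w["sigma_p"]);
  wp.delta = as<double>(w["delta"]);
  wp.cut345 = as<double>(w["cut345"]);
  wp.fmax = as<double>(w["f_max"]);
  wp.d_floor = 1e-3;
  // repulsive wall: V(d) = eps (sigma/d)^6, force F = 6 eps sigma^6 / d^7
  double s6 = std::pow(wp.sigma_rep, 6);
  wp.e_shift_rep = wp.eps * s6 / std::pow(wp.d_rep, 6);
  wp.f_shift_rep = 6.0 * wp.eps * s6 / std::pow(wp.d_rep, 7);
  // softened LJ: V(d) = 4 eps ((sp/(d+delta))^12 - (sp/(d+delta))^6)
  double xc = wp.sigma_p / (wp.cut345 + wp.delta);
  double x6 = std::pow(xc, 6);
  wp.e_shift_att = 4.0 * wp.eps * (x6 * x6 - x6);
  wp.f_shift_att = 24.0 * wp.eps / (wp.cut345 + wp.delta) * (2.0 * x6 * x6 - x6);
  // onset of the force cap: largest d with shifted force == fmax
  // repulsive wall (closed form): 6 eps sigma^6 / d^7 - f_shift = fmax
  wp.d_cap_rep = std::pow(6.0 * wp.eps * s6 / (wp.fmax + wp.f_shift_rep),
                          1.0 / 7.0);
  if (wp.d_cap_rep > wp.d_rep) wp.d_cap_rep = wp.d_rep;
  wp.v_cap_rep = wp.eps * s6 / std::pow(wp.d_cap_rep, 6) - wp.e_shift_rep -
                 wp.f_shift_rep * (wp.d_rep - wp.d_cap_rep);
  // softened LJ wall: bisection on (0, r_p], where the shifted force is
  // monotone decreasing from its d -> 0 limit to 0 at r_p
  auto fatt = [&wp](double d) {
    double x = wp.sigma_p / (d + wp.delta);
    double x6a = std::pow(x, 6);
    return 24.0 * wp.eps / (d + wp.delta) * (2.0 * x6a * x6a - x6a) -
           wp.f_shift_att;
  };
  if (fatt(0.0) <= wp.fmax) {
    wp.d_cap_att = 0.0;
  } else {
    double lo = 0.0, hi = wp.r_p;
    for (int it = 0; it < 200; ++it) {
      double mid = 0.5 * (lo + hi);
      if (fatt(mid) > wp.fmax) lo = mid; else hi = mid;
    }
    wp.d_cap_att = 0.5 * (lo + hi);
  }
  double xa = wp.sigma_p / (wp.d_cap_att + wp.delta);
  double xa6 = std::pow(xa, 6);
  wp.v_cap_att = 4.0 * wp.eps * (xa6 * xa6 - xa6) - wp.e_shift_att +
                 wp.f_shift_att * (wp.d_cap_att - wp.cut345);
  return wp;
}

// soft-min of distances from p to source points, with gradient
static double softmin_grad(const Vec3& p, const NumericMatrix& cj, double beta,
                           Vec3& grad) {
  int m = cj.nrow();
  std::vector<double> dj(m);
  double dmin = INF;
  for (int k = 0; k < m; ++k) {
    Vec3 d(p.x - cj(k, 0), p.y - cj(k, 1), p.z - cj(k, 2));
    dj[k] = d.norm();
    if (dj[k] < dmin) dmin = dj[k];
  }
  double sw = 0.0;
  Vec3 g;
  for (int k = 0; k < m; ++k) {
    double w = std::exp(-beta * (dj[k] - dmin));
    sw += w;
    double dk = std::max(dj[k], 1e-9);
    Vec3 u((p.x - cj(k, 0)) / dk, (p.y - cj(k, 1)) / dk, (p.z - cj(k, 2)) / dk);
    g = g + u * w;
  }
  grad = g * (1.0 / sw);
  return dmin - std::log(sw) / beta;
}

// [[Rcpp::export]]
double cpp_softmin(const NumericVector& d, double beta) {
  double dmin = INF;
  for (int i = 0; i < d.size(); ++i) dmin = std::min(dmin, d[i]);
  double sw = 0.0;
  for (int i = 0; i < d.size(); ++i) sw += std::exp(-beta * (d[i] - dmin));
  return dmin - std::log(sw) / beta;
}

// gated level-set value of a single wall at a point (Inf if not applicable)
static double phi_one(const Vec3& p, const WallPar& w, int wi, Vec3& grad) {
  grad = Vec3();
  if (!w.active[wi]) return INF;
  bool slab = w.active[4] && p.z > w.z_lo && p.z < w.z_hi;
  switch (wi) {
    case 0:  // phi1: upper planar wall, applies above the slab
      if (slab) return INF;
      if (p.z < w.z_hi && w.active[4]) return INF;
      grad = Vec3(0, 0, 1);
      return p.z - w.z_hi;
    case 1:  // phi2: lower planar wall, applies below the slab
      if (slab) return INF;
      if (p.z > w.z_lo && w.active[4]) return INF;
      grad = Vec3(0, 0, -1);
      return w.z_lo - p.z;
    case 2: {  // phi3: extracellular hemisphere
      if (slab || p.z < w.z_hi) return INF;
      Vec3 d(p.x - w.chi3[0], p.y - w.chi3[1], p.z - w.chi3[2]);
      double r = std::max(d.norm(), 1e-9);
      grad = d * (-1.0 / r);
      return w.r3 - r;
    }
    case 3: {  // phi4: cytoplasmic hemisphere
      if (slab || p.z > w.z_lo) return INF;
      Vec3 d(p.x - w.chi4[0], p.y - w.chi4[1], p.z - w.chi4[2]);
      double r = std::max(d.norm(), 1e-9);
      grad = d * (-1.0 / r);
      return w.r4 - r;
    }
    case 4: {  // phi5: membrane wall, applies inside the slab
      if (!slab) return INF;
      Vec3 gs;
      double s = softmin_grad(p, w.cj, w.beta, gs);
      grad = gs * -1.0;
      return w.r_p - s;
    }
  }
  return INF;
}

// min over applicable walls; fallback to ungated planar/hemisphere values if
// no wall applies at the point (e.g. below the base plane of a lone droplet)
static double wall_d(const Vec3& p, const WallPar& w, int& idx, Vec3& grad) {
  double best = INF;
  idx = -1;
  Vec3 g;
  for (int i = 0; i < 5; ++i) {
    Vec3 gi;
    double v = phi_one(p, w, i, gi);
    if (v < best) { best = v; idx = i; g = gi; }
  }
  if (idx < 0) {
    // ungated evaluation of the active planar walls
    for (int i = 0; i < 2; ++i) {
      if (!w.active[i]) continue;
      double v = (i == 0) ? p.z - w.z_hi : w.z_lo - p.z;
      if (v < best) { best = v; idx = i; g = (i == 0) ? Vec3(0, 0, 1) : Vec3(0, 0, -1); }
    }
  }
  grad = g;
  return best;
}

// [[Rcpp::export]]
List cpp_wall_distance(const NumericMatrix& pts, const List& wall) {
  WallPar w = parse_wall(wall);
  int n = pts.nrow();
  NumericVector d(n);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    Vec3 g;
    int wi;
    d[i] = wall_d(getv(pts, i), w, wi, g);
    idx[i] = wi + 1;
  }
  return List::create(_["d"] = d, _["wall"] = idx);
}

// gated phi_i at points, for cross-checking wall_distance
// [[Rcpp::export]]
NumericVector cpp_phi(const NumericMatrix& pts, const List& wall, int which) {
  WallPar w = parse_wall(wall);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 g;
    out[i] = phi_one(getv(pts, i), w, which - 1, g);
  }
  return out;
}

// energy-shifted boundary potential V_i(d): continuous, zero beyond cutoff,
// minimum of walls 3-5 exactly at d = r_p
static double wall_V(double d, int wi, const WallPar& w) {
  if (wi <= 1) {
    if (d >= w.d_rep) return 0.0;
    double de = std::max(d, w.d_floor);
    return w.eps * std::pow(w.sigma_rep / de, 6) - w.e_shift_rep;
  }
  if (d >= w.cut345) return 0.0;
  double de = std::max(d, w.d_floor);
  double x = w.sigma_p / (de + w.delta);
  double x6 = std::pow(x, 6);
  return 4.0 * w.eps * (x6 * x6 - x6) - w.e_shift_att;
}

// shifted, capped scalar force -dV/dd (positive pushes toward positive phi)
static double wall_F(double d, int wi, const WallPar& w) {
  double fm;
  if (wi <= 1) {
    if (d >= w.d_rep) return 0.0;
    if (d <= 0) return w.fmax;
    fm = 6.0 * w.eps * std::pow(w.sigma_rep, 6) / std::pow(d, 7) - w.f_shift_rep;
  } else {
    if (d >= w.cut345) return 0.0;
    if (d <= 0) return w.fmax;
    double x = w.sigma_p / (d + w.delta);
    double x6 = std::pow(x, 6);
    fm = 24.0 * w.eps / (d + w.delta) * (2.0 * x6 * x6 - x6) - w.f_shift_att;
  }
  if (fm > w.fmax) fm = w.fmax;
  if (fm < -w.fmax) fm = -w.fmax;
  return fm;
}

// force-consistent boundary potential: the exact antiderivative of the
// shifted, capped force wall_F (linear with slope fmax inside the cap
// region), zero beyond the cutoff. Used for the dynamics energy bookkeeping
// so that the reported potential matches the applied forces and the total
// energy is conserved; wall_V remains the energy-shifted reporting profile.
static double wall_Vdyn(double d, int wi, const WallPar& w) {
  if (wi <= 1) {
    if (d >= w.d_rep) return 0.0;
    if (d <= w.d_cap_rep)
      return w.v_cap_rep + w.fmax * (w.d_cap_rep - d);
    return w.eps * std::pow(w.sigma_rep / d, 6) - w.e_shift_rep -
           w.f_shift_rep * (w.d_rep - d);
  }
  if (d >= w.cut345) return 0.0;
  if (d <= w.d_cap_att)
    return w.v_cap_att + w.fmax * (w.d_cap_att - d);
  double x = w.sigma_p / (d + w.delta);
  double x6 = std::pow(x, 6);
  return 4.0 * w.eps * (x6 * x6 - x6) - w.e_shift_att +
         w.f_shift_att * (d - w.cut345);
}

// [[Rcpp::export]]
NumericVector cpp_wall_potential(const NumericVector& d, const IntegerVector& wi,
                                 const List& wall) {
  WallPar w = parse_wall(wall);
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = wall_V(d[i], wi[i] - 1, w);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_wall_force_scalar(const NumericVector& d, const IntegerVector& wi,
                                    const List& wall) {
  WallPar w = parse_wall(wall);
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = wall_F(d[i], wi[i] - 1, w);
  return out;
}

// per-atom coupling mode: 0 = gated minimum over all active walls (water);
// 1 = membrane wall phi5 only, ungated in z (protein C-alpha / aromatics),
// so a protein atom crossing the slab face never sees the water walls
// [[Rcpp::export]]
List cpp_wall_energy_forces(const NumericMatrix& pos, const List& wall,
                            const IntegerVector& coupled,
                            const IntegerVector& mode) {
  WallPar w = parse_wall(wall);
  int n = pos.nrow();
  NumericMatrix f(n, 3);
  double e = 0.0;
  bool have5 = w.active[4] && w.cj.nrow() > 0;
  for (int k = 0; k < coupled.size(); ++k) {
    int i = coupled[k];
    Vec3 g;
    int wi;
    double d;
    if (mode[k] == 1) {
      if (!have5) continue;
      Vec3 gs;
      double s = softmin_grad(getv(pos, i), w.cj, w.beta, gs);
      g = gs * -1.0;
      d = w.r_p - s;
      wi = 4;
    } else {
      d = wall_d(getv(pos, i), w, wi, g);
      if (wi < 0) continue;
    }
    e += wall_Vdyn(d, wi, w);
    double fm = wall_F(d, wi, w);
    addv(f, i, g * fm);
  }
  return List::create(_["energy"] = e, _["forces"] = f);
}

// ---------------------------------------------------------------------------
// SHAKE
// ---------------------------------------------------------------------------
// Iterative constraint solver: corrections along the reference bond vectors,
// mass-weighted. Convergence: | |r| - d0 | / d0 <= tol for every constraint.
// [[Rcpp::export]]
NumericMatrix cpp_shake(const NumericMatrix& xref, const NumericMatrix& xnew,
                        const IntegerMatrix& cp, const NumericVector& cd,
                        const NumericVector& invm, double tol, int maxit) {
  int m = cp.nrow();
  NumericMatrix x = clone(xnew);
  if (m == 0) return x;
  for (int it = 0; it < maxit; ++it) {
    bool done = true;
    double worst = 0.0;
    for (int c = 0; c < m; ++c) {
      int i = cp(c, 0), j = cp(c, 1);
      Vec3 r = getv(x, i) - getv(x, j);
      double r2 = r.dot(r), d2 = cd[c] * cd[c];
      double viol = std::fabs(std::sqrt(r2) - cd[c]) / cd[c];
      if (viol > worst) worst = viol;
      if (viol <= tol) continue;
      done = false;
      Vec3 rr = getv(xref, i) - getv(xref, j);
      double denom = 2.0 * (invm[i] + invm[j]) * rr.dot(r);
      if (std::fabs(denom) < 1e-12)
        stop("shake: degenerate constraint %d (reference bond orthogonal to current)", c + 1);
      double g = (r2 - d2) / denom;
      addv(x, i, rr * (-g * invm[i]));
      addv(x, j, rr * (g * invm[j]));
    }
    if (done) return x;
    if (it == maxit - 1)
      stop("shake: no convergence in %d iterations (worst relative violation %g)",
           maxit, worst);
  }
  return x;
}

// RATTLE velocity stage: iteratively remove the relative-velocity component
// along each constrained bond so velocities stay tangent to the constraint
// manifold (applied after every velocity update in the SD loop)
static void rattle_v(const NumericMatrix& x, NumericMatrix& v,
                     const IntegerMatrix& cp, const NumericVector& cd,
                     const NumericVector& invm, double tol, int maxit) {
  int m = cp.nrow();
  if (m == 0) return;
  for (int it = 0; it < maxit; ++it) {
    bool done = true;
    for (int c = 0; c < m; ++c) {
      int i = cp(c, 0), j = cp(c, 1);
      Vec3 r = getv(x, i) - getv(x, j);
      Vec3 dv = getv(v, i) - getv(v, j);
      double r2 = r.dot(r);
      double vrel = dv.dot(r);
      // tolerance on the relative velocity along the bond (nm/ps)
      if (std::fabs(vrel) / std::sqrt(r2) <= tol) continue;
      done = false;
      double lam = vrel / (r2 * (invm[i] + invm[j]));
      addv(v, i, r * (-lam * invm[i]));
      addv(v, j, r * (lam * invm[j]));
    }
    if (done) return;
    if (it == maxit - 1)
      stop("rattle: velocity constraints did not converge in %d iterations", maxit);
  }
  (void)cd;
}

// ---------------------------------------------------------------------------
// Full force/energy evaluation given a prebuilt nonbonded pair list
// ---------------------------------------------------------------------------
struct Topo {
  IntegerMatrix gob_p; NumericVector gob_k, gob_b;
  IntegerMatrix gom_p; NumericVector gom_b, gom_B, gom_v;
  IntegerMatrix cgb_p; NumericVector cgb_k, cgb_b;
  IntegerMatrix cgm_p; NumericVector cgm_b, cgm_B, cgm_v;
  IntegerMatrix bnd_p; NumericVector bnd_k, bnd_r;
  IntegerMatrix ang_t; NumericVector ang_k, ang_th;
  IntegerMatrix dih_q; NumericVector dih_k, dih_ph; IntegerVector dih_n;
  NumericVector sigma, eps, q, mass;
  IntegerVector group, atomistic_idx, excl_i, excl_j, cons_i, wall_idx, wall_mode;
  IntegerMatrix cons_p; NumericVector cons_d;
  double cutoff;
  bool pbc; NumericVector box;
};

static Topo parse_topo(const List& t) {
  Topo o;
  o.gob_p = as<IntegerMatrix>(t["gob_p"]); o.gob_k = t["gob_k"]; o.gob_b = t["gob_b"];
  o.gom_p = as<IntegerMatrix>(t["gom_p"]); o.gom_b = t["gom_b"]; o.gom_B = t["gom_B"]; o.gom_v = t["gom_v"];
  o.cgb_p = as<IntegerMatrix>(t["cgb_p"]); o.cgb_k = t["cgb_k"]; o.cgb_b = t["cgb_b"];
  o.cgm_p = as<IntegerMatrix>(t["cgm_p"]); o.cgm_b = t["cgm_b"]; o.cgm_B = t["cgm_B"]; o.cgm_v = t["cgm_v"];
  o.bnd_p = as<IntegerMatrix>(t["bnd_p"]); o.bnd_k = t["bnd_k"]; o.bnd_r = t["bnd_r"];
  o.ang_t = as<IntegerMatrix>(t["ang_t"]); o.ang_k = t["ang_k"]; o.ang_th = t["ang_th"];
  o.dih_q = as<IntegerMatrix>(t["dih_q"]); o.dih_k = t["dih_k"]; o.dih_n = t["dih_n"]; o.dih_ph = t["dih_ph"];
  o.sigma = t["sigma"]; o.eps = t["eps"]; o.q = t["q"]; o.mass = t["mass"];
  o.group = t["group"];
  o.atomistic_idx = t["atomistic_idx"];
  o.excl_i = t["excl_i"]; o.excl_j = t["excl_j"];
  o.cons_p = as<IntegerMatrix>(t["cons_p"]); o.cons_d = t["cons_d"];
  o.wall_idx = t["wall_idx"];
  o.wall_mode = t["wall_mode"];
  o.cutoff = as<double>(t["cutoff"]);
  o.pbc = as<bool>(t["pbc"]);
  o.box = t["box"];
  return o;
}

// returns energies (named) and forces; wall may be R_NilValue
static void eval_all(const NumericMatrix& pos, const Topo& t, const List& topo,
                     SEXP wall, const IntegerMatrix& nbp, NumericVector& ener,
                     NumericMatrix& f) {
  int n = pos.nrow();
  std::fill(f.begin(), f.end(), 0.0);
  List gb = cpp_go_bonded(pos, t.gob_p, t.gob_k, t.gob_b);
  List gm = cpp_go_morse(pos, t.gom_p, t.gom_b, t.gom_B, t.gom_v);
  List cb = cpp_go_bonded(pos, t.cgb_p, t.cgb_k, t.cgb_b);
  List cm = cpp_go_morse(pos, t.cgm_p, t.cgm_b, t.cgm_B, t.cgm_v);
  List mb = cpp_mm_bonded(pos, t.bnd_p, t.bnd_k, t.bnd_r, t.ang_t, t.ang_k,
                          t.ang_th, t.dih_q, t.dih_k, t.dih_n, t.dih_ph, t.group);
  List nb = cpp_nonbonded(pos, nbp, t.sigma, t.eps, t.q, t.cutoff, t.group,
                          t.pbc, t.box);
  double e_cg = as<double>(gb["energy"]) + as<double>(gm["energy"]);
  double e_cgi = as<double>(cb["energy"]) + as<double>(cm["energy"]);
  double e_mm = as<double>(mb["e_mm"]) + as<double>(nb["e_mm"]);
  double e_i = as<double>(mb["e_i"]) + as<double>(nb["e_i"]);
  double e_mmi = as<double>(mb["e_mmi"]) + as<double>(nb["e_mmi"]);
  double e_wall = 0.0;
  NumericMatrix fw;
  bool has_wall = !Rf_isNull(wall);
  if (has_wall) {
    List wres = cpp_wall_energy_forces(pos, as<List>(wall), t.wall_idx,
                                       t.wall_mode);
    e_wall = as<double>(wres["energy"]);
    fw = as<NumericMatrix>(wres["forces"]);
  }
  NumericMatrix f1 = gb["forces"], f2 = gm["forces"], f3 = cb["forces"],
                f4 = cm["forces"], f5 = mb["forces"], f6 = nb["forces"];
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = f1(i, k) + f2(i, k) + f3(i, k) + f4(i, k) + f5(i, k) + f6(i, k);
      if (has_wall) v += fw(i, k);
      f(i, k) = v;
    }
  ener["e_mm"] = e_mm; ener["e_i"] = e_i; ener["e_mmi"] = e_mmi;
  ener["e_cg"] = e_cg; ener["e_cgi"] = e_cgi; ener["e_wall"] = e_wall;
  ener["e_pot"] = e_mm + e_i + e_mmi + e_cg + e_cgi + e_wall;
}

// [[Rcpp::export]]
List cpp_eval_all(const NumericMatrix& pos, const List& topo, SEXP wall,
                  const IntegerMatrix& nbp) {
  Topo t = parse_topo(topo);
  NumericVector ener = NumericVector::create(
      _["e_mm"] = 0.0, _["e_i"] = 0.0, _["e_mmi"] = 0.0, _["e_cg"] = 0.0,
      _["e_cgi"] = 0.0, _["e_wall"] = 0.0, _["e_pot"] = 0.0);
  NumericMatrix f(pos.nrow(), 3);
  eval_all(pos, t, topo, wall, nbp, ener, f);
  return List::create(_["energies"] = ener, _["forces"] = f);
}

// ---------------------------------------------------------------------------
// Stochastic dynamics: symmetric Langevin velocity-Verlet (OBABO splitting),
// reducing exactly to velocity-Verlet at zero friction. SHAKE after the
// position update with a matching velocity correction.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_sd(const NumericMatrix& pos0, const NumericMatrix& vel0,
                const List& topo, SEXP wall, double dt, int nsteps,
                double temperature, double tau, int out_stride, int vel_stride,
                int nb_rebuild, double skin, double shake_tol, int shake_maxit,
                int ndof) {
  Topo t = parse_topo(topo);
  int n = pos0.nrow();
  NumericMatrix x = clone(pos0), v = clone(vel0);
  NumericVector invm(n);
  for (int i = 0; i < n; ++i) invm[i] = 1.0 / t.mass[i];
  double gamma = (tau > 0) ? 1.0 / tau : 0.0;
  double c1 = std::exp(-gamma * dt / 2.0);
  double kT = KB * temperature;
  NumericVector c2(n);
  for (int i = 0; i < n; ++i)
    c2[i] = (gamma > 0 && temperature > 0)
                ? std::sqrt(kT * (1.0 - c1 * c1) * invm[i])
                : 0.0;

  IntegerMatrix nbp = cpp_build_pairs(x, t.atomistic_idx, t.cutoff + skin,
                                      t.excl_i, t.excl_j, t.pbc, t.box);
  NumericVector ener = NumericVector::create(
      _["e_mm"] = 0.0, _["e_i"] = 0.0, _["e_mmi"] = 0.0, _["e_cg"] = 0.0,
      _["e_cgi"] = 0.0, _["e_wall"] = 0.0, _["e_pot"] = 0.0);
  NumericMatrix f(n, 3);
  eval_all(x, t, topo, wall, nbp, ener, f);

  int nfr = nsteps / std::max(1, out_stride) + 1;
  int nvf = (vel_stride > 0) ? nsteps / vel_stride + 1 : 0;
  NumericVector frames(Dimension(n, 3, nfr));
  NumericVector vframes(Dimension(n, 3, std::max(1, nvf)));
  NumericVector ftimes(nfr), vtimes(std::max(1, nvf));
  NumericMatrix etab(nfr, 11);  // time,e_mm,e_i,e_mmi,e_cg,e_cgi,e_wall,pot,kin,T,total
  int fr = 0, vf = 0;

  auto kinetic = [&](void) {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * t.mass[i] *
            (v(i, 0) * v(i, 0) + v(i, 1) * v(i, 1) + v(i, 2) * v(i, 2));
    return ke;
  };
  auto record = [&](int step) {
    double tm = step * dt;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) frames[i + n * k + 3 * n * fr] = x(i, k);
    ftimes[fr] = tm;
    double ke = kinetic();
    etab(fr, 0) = tm;
    for (int k = 0; k < 7; ++k) etab(fr, 1 + k) = ener[k];
    etab(fr, 8) = ke;
    etab(fr, 9) = (ndof > 0) ? 2.0 * ke / (ndof * KB) : 0.0;
    etab(fr, 10) = ener["e_pot"] + ke;
    ++fr;
  };
  auto vrecord = [&](int step) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) vframes[i + n * k + 3 * n * vf] = v(i, k);
    vtimes[vf] = step * dt;
    ++vf;
  };

  record(0);
  if (vel_stride > 0) vrecord(0);

  bool cons = t.cons_p.nrow() > 0;
  auto fixv = [&](void) {
    if (cons) rattle_v(x, v, t.cons_p, t.cons_d, invm, 1e-10, shake_maxit);
  };
  fixv();  // project initial velocities onto the constraint manifold

  NumericMatrix xold(n, 3);
  for (int step = 1; step <= nsteps; ++step) {
    // O half
    if (gamma > 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          v(i, k) = c1 * v(i, k) + c2[i] * norm_rand();
      fixv();
    }
    // B half
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v(i, k) += 0.5 * dt * f(i, k) * invm[i];
    // A (+ SHAKE)
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        xold(i, k) = x(i, k);
        x(i, k) += dt * v(i, k);
      }
    if (t.cons_p.nrow() > 0) {
      NumericMatrix xc = cpp_shake(xold, x, t.cons_p, t.cons_d, invm, shake_tol,
                                   shake_maxit);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          v(i, k) += (xc(i, k) - x(i, k)) / dt;
          x(i, k) = xc(i, k);
        }
    }
    if (nb_rebuild > 0 && step % nb_rebuild == 0)
      nbp = cpp_build_pairs(x, t.atomistic_idx, t.cutoff + skin, t.excl_i,
                            t.excl_j, t.pbc, t.box);
    eval_all(x, t, topo, wall, nbp, ener, f);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        if (!std::isfinite(f(i, k)) || !std::isfinite(x(i, k)))
          stop("sd_step: non-finite force/position at atom %d, step %d", i + 1, step);
    // B half
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v(i, k) += 0.5 * dt * f(i, k) * invm[i];
    fixv();
    // O half
    if (gamma > 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          v(i, k) = c1 * v(i, k) + c2[i] * norm_rand();
      fixv();
    }

    if (out_stride > 0 && step % out_stride == 0) record(step);
    if (vel_stride > 0 && step % vel_stride == 0) vrecord(step);
  }

  double ke = kinetic();
  return List::create(
      _["positions"] = x, _["velocities"] = v, _["forces"] = f,
      _["frames"] = frames, _["frame_times"] = ftimes,
      _["vframes"] = (vel_stride > 0 ? vframes : NumericVector(0)),
      _["vtimes"] = (vel_stride > 0 ? vtimes : NumericVector(0)),
      _["energies"] = etab, _["n_frames"] = fr, _["n_vframes"] = vf,
      _["kinetic"] = ke,
      _["temperature"] = (ndof > 0) ? 2.0 * ke / (ndof * KB) : 0.0);
}
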