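// Hot-path kernels: minimum-image pair search, HPS/Debye-Hueckel/bond
// force evaluation over precomputed pair lists, and a chunked BAOAB
// Langevin integrator that advances until the neighbor-list buffer is
// half consumed. Units: kcal/mol, Angstrom, fs, Da, elementary charge.
// Coordinates are kept wrapped inside the box so the minimum image
// reduces to a single-branch correction.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KE_CONV = 2390.0574; // 1 Da A^2/fs^2 in kcal/mol
static const double KB = 0.0019872041;   // kcal/mol/K
static const double SWITCH2 = 1.2599210498948732; // 2^(1/3): (2^(1/6))^2

// counter-based noise: splitmix64 hash + Box-Muller, keyed on
// (seed, absolute step, particle) so trajectories are independent of
// chunk boundaries and rebuild/rebalance schedules
static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t z) {
  // (0, 1]: avoids log(0) in Box-Muller
  return (double)((z >> 11) + 1) * (1.0 / 9007199254740993.0);
}

static inline void gauss3(uint64_t seed, uint64_t step, uint64_t particle,
                          double *g) {
  uint64_t k = splitmix64(seed ^ splitmix64(step) ^
                          splitmix64(particle * 0x9E3779B97F4A7C15ULL));
  uint64_t z1 = splitmix64(k), z2 = splitmix64(z1), z3 = splitmix64(z2),
           z4 = splitmix64(z3);
  double r1 = std::sqrt(-2.0 * std::log(u01(z1)));
  double a1 = 2.0 * M_PI * u01(z2);
  double r2 = std::sqrt(-2.0 * std::log(u01(z3)));
  double a2 = 2.0 * M_PI * u01(z4);
  g[0] = r1 * std::cos(a1);
  g[1] = r1 * std::sin(a1);
  g[2] = r2 * std::cos(a2);
}

// minimum image via round: correct for arbitrary separations
static inline double mi(double d, double box) {
  return d - box * std::round(d / box);
}

// single-branch minimum image: valid when |d| < 1.5 box (wrapped inputs)
static inline double mib(double d, double box, double hbox) {
  if (d > hbox) return d - box;
  if (d < -hbox) return d + box;
  return d;
}

// [[Rcpp::export]]
List cpp_pairs_within(NumericMatrix x, NumericVector box, double rmax) {
  const int n = x.nrow();
  std::vector<int> pi, pj;
  std::vector<double> pr;
  pi.reserve(1024); pj.reserve(1024); pr.reserve(1024);
  const double r2max = rmax * rmax;
  const double bx = box[0], by = box[1], bz = box[2];
  const double hx = bx / 2, hy = by / 2, hz = bz / 2;
  // wrapped copy so the single-branch minimum image is exact
  std::vector<double> wx(n), wy(n), wz(n);
  for (int a = 0; a < n; ++a) {
    wx[a] = x(a,0) - bx * std::floor(x(a,0) / bx);
    wy[a] = x(a,1) - by * std::floor(x(a,1) / by);
    wz[a] = x(a,2) - bz * std::floor(x(a,2) / bz);
  }
  for (int a = 0; a < n - 1; ++a) {
    const double xa = wx[a], ya = wy[a], za = wz[a];
    for (int b = a + 1; b < n; ++b) {
      double dx = mib(xa - wx[b], bx, hx);
      double dy = mib(ya - wy[b], by, hy);
      double dz = mib(za - wz[b], bz, hz);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < r2max) {
        pi.push_back(a + 1); pj.push_back(b + 1);
        pr.push_back(std::sqrt(r2));
      }
    }
  }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["r"] = wrap(pr));
}

struct PairTables {
  IntegerVector bi, bj;          // harmonic bonds
  NumericVector bk, bb0;
  IntegerVector hi, hj;          // HPS pairs
  NumericVector hsig, hlam;
  double heps, rc_hps;
  IntegerVector ei, ej;          // electrostatic pairs
  NumericVector eqq;             // kC qi qj / eps_r, kcal*A/mol
  double lambda_d, rc_ele;
};

// forces (kcal/mol/A) and per-class energies for bonds + HPS + DH;
// assumes wrapped coordinates (branch minimum image)
static void eval_forces(const NumericMatrix &x, const double *box,
                        const double *hbox, const PairTables &pt,
                        NumericMatrix &F,
                        double &e_bond, double &e_hps, double &e_ele) {
  std::fill(F.begin(), F.end(), 0.0);
  e_bond = e_hps = e_ele = 0.0;
  const int nb = pt.bi.size();
  for (int t = 0; t < nb; ++t) {
    int a = pt.bi[t] - 1, b = pt.bj[t] - 1;
    double dx = mib(x(a,0) - x(b,0), box[0], hbox[0]);
    double dy = mib(x(a,1) - x(b,1), box[1], hbox[1]);
    double dz = mib(x(a,2) - x(b,2), box[2], hbox[2]);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double db = r - pt.bb0[t];
    e_bond += pt.bk[t] * db * db;
    double de = 2.0 * pt.bk[t] * db / r; // dE/dr / r
    F(a,0) -= de * dx; F(a,1) -= de * dy; F(a,2) -= de * dz;
    F(b,0) += de * dx; F(b,1) += de * dy; F(b,2) += de * dz;
  }
  const double rc2 = pt.rc_hps * pt.rc_hps;
  const double heps = pt.heps;
  const int nh = pt.hi.size();
  const int *hi = INTEGER(pt.hi), *hj = INTEGER(pt.hj);
  const double *hsig = REAL(pt.hsig), *hlam = REAL(pt.hlam);
  for (int t = 0; t < nh; ++t) {
    int a = hi[t] - 1, b = hj[t] - 1;
    double dx = mib(x(a,0) - x(b,0), box[0], hbox[0]);
    double dy = mib(x(a,1) - x(b,1), box[1], hbox[1]);
    double dz = mib(x(a,2) - x(b,2), box[2], hbox[2]);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rc2) continue;
    double sig = hsig[t], lam = hlam[t];
    double s2 = sig * sig / r2;
    double s6 = s2 * s2 * s2;
    double elj = 4.0 * heps * (s6 * s6 - s6);
    double delj_r = 24.0 * heps * (s6 - 2.0 * s6 * s6) / r2; // dE/dr / r
    double e, de_r;
    if (r2 <= SWITCH2 * sig * sig) { // r <= 2^(1/6) sigma
      e = elj + (1.0 - lam) * heps;
      de_r = delj_r;
    } else {
      e = lam * elj;
      de_r = lam * delj_r;
    }
    e_hps += e;
    F(a,0) -= de_r * dx; F(a,1) -= de_r * dy; F(a,2) -= de_r * dz;
    F(b,0) += de_r * dx; F(b,1) += de_r * dy; F(b,2) += de_r * dz;
  }
  const double rce2 = pt.rc_ele * pt.rc_ele;
  const int ne = pt.ei.size();
  for (int t = 0; t < ne; ++t) {
    int a = pt.ei[t] - 1, b = pt.ej[t] - 1;
    double dx = mib(x(a,0) - x(b,0), box[0], hbox[0]);
    double dy = mib(x(a,1) - x(b,1), box[1], hbox[1]);
    double dz = mib(x(a,2) - x(b,2), box[2], hbox[2]);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rce2) continue;
    double r = std::sqrt(r2);
    double e = pt.eqq[t] * std::exp(-r / pt.lambda_d) / r;
    e_ele += e;
    double de_r = -e * (1.0 / r + 1.0 / pt.lambda_d) / r;
    F(a,0) -= de_r * dx; F(a,1) -= de_r * dy; F(a,2) -= de_r * dz;
    F(b,0) += de_r * dx; F(b,1) += de_r * dy; F(b,2) += de_r * dz;
  }
}

static PairTables make_tables(List bonds, List hps, List ele,
                              double hps_eps, double rc_hps,
                              double lambda_d, double rc_ele) {
  PairTables pt;
  pt.bi = bonds["i"]; pt.bj = bonds["j"];
  pt.bk = bonds["k"]; pt.bb0 = bonds["b0"];
  pt.hi = hps["i"]; pt.hj = hps["j"];
  pt.hsig = hps["sigma"]; pt.hlam = hps["lambda"];
  pt.heps = hps_eps; pt.rc_hps = rc_hps;
  pt.ei = ele["i"]; pt.ej = ele["j"]; pt.eqq = ele["qq"];
  pt.lambda_d = lambda_d; pt.rc_ele = rc_ele;
  return pt;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix x, NumericVector box,
                       List bonds, List hps, List ele,
                       double hps_eps, double rc_hps,
                       double lambda_d, double rc_ele) {
  PairTables pt = make_tables(bonds, hps, ele, hps_eps, rc_hps,
                              lambda_d, rc_ele);
  const int n = x.nrow();
  // wrap a copy so the branch minimum image is exact
  NumericMatrix X = clone(x);
  double bx[3] = {box[0], box[1], box[2]};
  double hbox[3] = {bx[0] / 2, bx[1] / 2, bx[2] / 2};
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c)
      X(a,c) -= bx[c] * std::floor(X(a,c) / bx[c]);
  NumericMatrix F(n, 3);
  double eb, eh, ee;
  eval_forces(X, bx, hbox, pt, F, eb, eh, ee);
  return List::create(_["e_bond"] = eb, _["e_hps"] = eh, _["e_ele"] = ee,
                      _["forces"] = F);
}

// BAOAB map iterated with one force evaluation per step:
//   v += dt F/m ; x += dt/2 v ; v = c1 v + c2 xi ; x += dt/2 v
// Runs until max_steps or until the maximum minimum-image displacement
// from ref_x reaches half_buffer (checked before each step so forces are
// never evaluated with a stale list). Coordinates are wrapped into the
// box on entry and after every step.
// [[Rcpp::export]]
List cpp_langevin_chunk(NumericMatrix x, NumericMatrix v,
                        NumericVector mass, NumericVector box,
                        List bonds, List hps, List ele,
                        double hps_eps, double rc_hps,
                        double lambda_d, double rc_ele,
                        double dt, double gamma_ps, double temperature,
                        int max_steps, double half_buffer,
                        NumericMatrix ref_x, double seed, double step0) {
  const int n = x.nrow();
  PairTables pt = make_tables(bonds, hps, ele, hps_eps, rc_hps,
                              lambda_d, rc_ele);
  NumericMatrix X = clone(x), V = clone(v), F(n, 3), R = clone(ref_x);
  double bx[3] = {box[0], box[1], box[2]};
  double hbox[3] = {bx[0] / 2, bx[1] / 2, bx[2] / 2};
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) {
      X(a,c) -= bx[c] * std::floor(X(a,c) / bx[c]);
      R(a,c) -= bx[c] * std::floor(R(a,c) / bx[c]);
    }
  double gamma_fs = gamma_ps * 1e-3;
  double c1 = std::exp(-gamma_fs * dt);
  std::vector<double> inv_mc(n), sig_v(n);
  for (int a = 0; a < n; ++a) {
    inv_mc[a] = 1.0 / (mass[a] * KE_CONV);
    sig_v[a] = std::sqrt(KB * temperature * (1.0 - c1 * c1) * inv_mc[a]);
  }
  const uint64_t seed64 = (uint64_t) seed;
  const uint64_t s0 = (uint64_t) step0;
  const double hb2 = half_buffer * half_buffer;
  double eb, eh, ee;
  int done = 0;
  bool need_rebuild = false;
  for (int s = 0; s < max_steps; ++s) {
    // buffer check against the list's reference coordinates
    double maxd2 = 0.0;
    for (int a = 0; a < n; ++a) {
      double dx = mib(X(a,0) - R(a,0), bx[0], hbox[0]);
      double dy = mib(X(a,1) - R(a,1), bx[1], hbox[1]);
      double dz = mib(X(a,2) - R(a,2), bx[2], hbox[2]);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 >= hb2) { need_rebuild = true; break; }
    eval_forces(X, bx, hbox, pt, F, eb, eh, ee);
    for (int a = 0; a < n; ++a) {
      for (int c = 0; c < 3; ++c) {
        if (!std::isfinite(F(a,c)))
          stop("non-finite force on particle %d", a + 1);
        V(a,c) += dt * F(a,c) * inv_mc[a];
        X(a,c) += 0.5 * dt * V(a,c);
      }
      double g[3];
      gauss3(seed64, s0 + (uint64_t) s, (uint64_t) a, g);
      V(a,0) = c1 * V(a,0) + sig_v[a] * g[0];
      V(a,1) = c1 * V(a,1) + sig_v[a] * g[1];
      V(a,2) = c1 * V(a,2) + sig_v[a] * g[2];
      for (int c = 0; c < 3; ++c) {
        X(a,c) += 0.5 * dt * V(a,c);
        X(a,c) -= bx[c] * std::floor(X(a,c) / bx[c]);
      }
    }
    ++done;
  }
  return List::create(_["x"] = X, _["v"] = V, _["steps"] = done,
                      _["need_rebuild"] = need_rebuild);
}
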