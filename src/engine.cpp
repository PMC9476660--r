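// Core energy/force evaluation and Langevin propagation for the
// coarse-grained implicit water-membrane model.
//
// Units: kcal/mol (energy), Angstrom (length), fs (time), amu (mass),
// elementary charge (charge).  All pairwise loops are O(N^2); the systems
// this package targets at desk scale are a few hundred beads at most.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SQRTPI = 1.7724538509055160273;
static const double KELEC  = 332.0636;     // kcal A / (mol e^2)
static const double KB     = 0.0019872041; // kcal/mol/K
static const double FCONV  = 4.184e-4;     // (kcal/mol/A)/amu -> A/fs^2

struct Membrane {
  bool on;
  double T, nexp, a;
};

// switching f(z') = z'^n / (1 + z'^n), z' = |z|/(T/2); 0 in the membrane
// core, 0.5 at |z| = T/2, -> 1 in bulk water.
static inline double fswitch(double z, const Membrane& m) {
  if (!m.on) return 1.0;
  double zp = std::fabs(z) / (m.T / 2.0);
  if (zp == 0.0) return 0.0;
  double zn = std::pow(zp, m.nexp);
  return zn / (1.0 + zn);
}

static inline double dfswitch(double z, const Membrane& m) {
  if (!m.on) return 0.0;
  double s = (z >= 0.0) ? 1.0 : -1.0;
  double half = m.T / 2.0;
  double zp = std::fabs(z) / half;
  if (zp <= 0.0) return 0.0;
  double zn1 = std::pow(zp, m.nexp - 1.0);
  double zn  = zn1 * zp;
  double den = 1.0 + zn;
  return s * (m.nexp / half) * zn1 / (den * den);
}

struct System {
  int n;
  std::vector<int> type;
  std::vector<double> charge, mass;
  // per-bead solvation columns: Vw Vc lw lc grefw grefc gfw gfc R
  NumericMatrix solv;
  NumericMatrix lj_eps, lj_sig; // ntype x ntype
  std::vector<char> excl;       // n*n bonded exclusions (LJ/elec)
  NumericMatrix bonds;          // i j r0 k
  NumericMatrix angles;         // i j k cos0 kf
  NumericMatrix dihedrals;      // i j k l phis kf mult
  NumericMatrix restraints;     // kx ky kz x0 y0 z0 (0 rows = none)
  Membrane mem;
  bool interp_all;
  double r_on, r_off, cut_solv;
};

static System build_system(const List& s) {
  System sys;
  IntegerVector ty = s["type"];
  NumericVector q = s["charge"], ms = s["mass"];
  sys.n = ty.size();
  sys.type.assign(ty.begin(), ty.end());
  sys.charge.assign(q.begin(), q.end());
  sys.mass.assign(ms.begin(), ms.end());
  sys.solv = as<NumericMatrix>(s["solv"]);
  sys.lj_eps = as<NumericMatrix>(s["lj_eps"]);
  sys.lj_sig = as<NumericMatrix>(s["lj_sig"]);
  IntegerMatrix ep = as<IntegerMatrix>(s["excl_pairs"]); // 0-based i,j
  sys.excl.assign((size_t)sys.n * sys.n, 0);
  for (int r = 0; r < ep.nrow(); ++r) {
    int i = ep(r, 0), j = ep(r, 1);
    sys.excl[(size_t)i * sys.n + j] = 1;
    sys.excl[(size_t)j * sys.n + i] = 1;
  }
  sys.bonds = as<NumericMatrix>(s["bonds"]);
  sys.angles = as<NumericMatrix>(s["angles"]);
  sys.dihedrals = as<NumericMatrix>(s["dihedrals"]);
  sys.restraints = as<NumericMatrix>(s["restraints"]);
  List mm = s["membrane"];
  sys.mem.on = as<bool>(mm["on"]);
  sys.mem.T = as<double>(mm["thickness"]);
  sys.mem.nexp = as<double>(mm["n"]);
  sys.mem.a = as<double>(mm["a"]);
  sys.interp_all = as<bool>(s["interp_all"]);
  sys.r_on = as<double>(s["r_on"]);
  sys.r_off = as<double>(s["r_off"]);
  sys.cut_solv = as<double>(s["cut_solv"]);
  return sys;
}

// CHARMM energy switching on [r_on, r_off]; C1-continuous at both ends.
static inline void sw(double r, double ron, double roff, double& S, double& dS) {
  if (r <= ron) { S = 1.0; dS = 0.0; return; }
  if (r >= roff) { S = 0.0; dS = 0.0; return; }
  double r2 = r * r, ron2 = ron * ron, roff2 = roff * roff;
  double u = roff2 - r2, w = roff2 + 2.0 * r2 - 3.0 * ron2;
  double D = (roff2 - ron2); D = D * D * D;
  S = u * u * w / D;
  dS = 4.0 * r * u * (u - w) / D;
}

struct Energies {
  double bond = 0, angle = 0, dihedral = 0, lj = 0, elec = 0, solv = 0,
         restraint = 0;
  double total() const {
    return bond + angle + dihedral + lj + elec + solv + restraint;
  }
};

// Full potential + analytic gradient.  pos/frc are length 3n (x,y,z per bead).
static Energies compute(const System& S, const std::vector<double>& pos,
                        std::vector<double>& frc,
                        std::vector<double>* per_bead_solv = nullptr,
                        bool check_overlap = true) {
  const int n = S.n;
  Energies E;
  std::fill(frc.begin(), frc.end(), 0.0);

  // per-bead environment-dependent solvation parameters
  std::vector<double> fi(n), dfi(n), lam(n), dlam(n), gfree(n), dgfree(n),
      Vi(n), dVi(n), alpha(n), dalpha(n);
  for (int i = 0; i < n; ++i) {
    double z = pos[3 * i + 2];
    double f = fswitch(z, S.mem), df = dfswitch(z, S.mem);
    fi[i] = f; dfi[i] = df;
    double Vw = S.solv(i, 0), Vc = S.solv(i, 1);
    double lw = S.solv(i, 2), lc = S.solv(i, 3);
    double gfw = S.solv(i, 6), gfc = S.solv(i, 7);
    if (S.interp_all) {
      lam[i] = f * lw + (1 - f) * lc;   dlam[i] = df * (lw - lc);
      gfree[i] = f * gfw + (1 - f) * gfc; dgfree[i] = df * (gfw - gfc);
      Vi[i] = f * Vw + (1 - f) * Vc;    dVi[i] = df * (Vw - Vc);
    } else {
      lam[i] = lw; dlam[i] = 0; gfree[i] = gfw; dgfree[i] = 0;
      Vi[i] = Vw; dVi[i] = 0;
    }
    alpha[i] = 2.0 * gfree[i] / (SQRTPI * lam[i]);
    dalpha[i] = 2.0 * (dgfree[i] * lam[i] - gfree[i] * dlam[i]) /
                (SQRTPI * lam[i] * lam[i]);
    // reference solvation term (z-interpolated between water and chex)
    double grw = S.solv(i, 4), grc = S.solv(i, 5);
    double gref = f * grw + (1 - f) * grc;
    E.solv += gref;
    frc[3 * i + 2] -= df * (grw - grc);
    if (per_bead_solv) (*per_bead_solv)[i] = gref;
  }

  // nonbonded pair loop: LJ, electrostatics, solvation exclusion
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos[3 * i] - pos[3 * j];
      double dy = pos[3 * i + 1] - pos[3 * j + 1];
      double dz = pos[3 * i + 2] - pos[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (check_overlap && r < 0.1)
        stop("overlapping beads (r < 0.1 A) between beads %d and %d",
             i + 1, j + 1);
      double dEdr = 0.0; // accumulated radial derivative for this pair
      bool excl = S.excl[(size_t)i * n + j] != 0;

      if (!excl && r < S.r_off) {
        double Ssw, dSsw;
        sw(r, S.r_on, S.r_off, Ssw, dSsw);
        // Lennard-Jones 12-6
        double sig = S.lj_sig(S.type[i], S.type[j]);
        double eps = S.lj_eps(S.type[i], S.type[j]);
        if (eps > 0) {
          double sr2 = sig * sig / r2;
          double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
          double e0 = 4.0 * eps * (sr12 - sr6);
          double de0 = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
          E.lj += e0 * Ssw;
          dEdr += de0 * Ssw + e0 * dSsw;
        }
        // electrostatics with membrane-attenuated distance dielectric:
        // eps(r) = r^p, p = a + (1-a) sqrt(f_i f_j)  =>  E = C q q r^-(1+p)
        double qq = S.charge[i] * S.charge[j];
        if (qq != 0.0) {
          double s = std::sqrt(fi[i] * fi[j]);
          double p = S.mem.a + (1.0 - S.mem.a) * s;
          double e0 = KELEC * qq * std::pow(r, -(1.0 + p));
          double de0 = -(1.0 + p) * e0 / r;
          double dedp = -e0 * std::log(r);
          E.elec += e0 * Ssw;
          dEdr += de0 * Ssw + e0 * dSsw;
          if (s > 1e-14) {
            double c = dedp * (1.0 - S.mem.a) / (2.0 * s) * Ssw;
            frc[3 * i + 2] -= c * fi[j] * dfi[i];
            frc[3 * j + 2] -= c * fi[i] * dfi[j];
          }
        }
      }

      // Gaussian solvent-exclusion correction (no bonded exclusions)
      if (r < S.cut_solv) {
        for (int pass = 0; pass < 2; ++pass) {
          int a = pass == 0 ? i : j; // solvated bead
          int b = pass == 0 ? j : i; // occluder
          double Ra = S.solv(a, 8);
          double x = (r - Ra) / lam[a];
          double ex = std::exp(-x * x);
          double h = alpha[a] * ex / (4.0 * M_PI * r2);
          double corr = h * Vi[b];
          E.solv -= corr;
          if (per_bead_solv) (*per_bead_solv)[a] -= corr;
          // radial derivative of -corr
          dEdr -= corr * (-2.0 / r - 2.0 * x / lam[a]);
          // z-derivatives through the environment interpolation
          double dcorr_dza = Vi[b] * ex / (4.0 * M_PI * r2) * dalpha[a] +
                             corr * (2.0 * x * x * dlam[a] / lam[a]);
          double dcorr_dzb = h * dVi[b];
          frc[3 * a + 2] += dcorr_dza;
          frc[3 * b + 2] += dcorr_dzb;
        }
      }

      if (dEdr != 0.0) {
        double g = dEdr / r;
        frc[3 * i] -= g * dx;     frc[3 * j] += g * dx;
        frc[3 * i + 1] -= g * dy; frc[3 * j + 1] += g * dy;
        frc[3 * i + 2] -= g * dz; frc[3 * j + 2] += g * dz;
      }
    }
  }

  // bonds: E = k (r - r0)^2
  for (int b = 0; b < S.bonds.nrow(); ++b) {
    int i = (int)S.bonds(b, 0), j = (int)S.bonds(b, 1);
    double r0 = S.bonds(b, 2), k = S.bonds(b, 3);
    double dx = pos[3 * i] - pos[3 * j];
    double dy = pos[3 * i + 1] - pos[3 * j + 1];
    double dz = pos[3 * i + 2] - pos[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - r0;
    E.bond += k * d * d;
    double g = 2.0 * k * d / r;
    frc[3 * i] -= g * dx;     frc[3 * j] += g * dx;
    frc[3 * i + 1] -= g * dy; frc[3 * j + 1] += g * dy;
    frc[3 * i + 2] -= g * dz; frc[3 * j + 2] += g * dz;
  }

  // angles: cosine-harmonic E = k (cos th - cos th0)^2 (no 1/sin
  // singularity, so collinear geometries stay finite)
  for (int a = 0; a < S.angles.nrow(); ++a) {
    int i = (int)S.angles(a, 0), j = (int)S.angles(a, 1), k = (int)S.angles(a, 2);
    double c0 = S.angles(a, 3), kf = S.angles(a, 4);
    double ux = pos[3 * i] - pos[3 * j], uy = pos[3 * i + 1] - pos[3 * j + 1],
           uz = pos[3 * i + 2] - pos[3 * j + 2];
    double vx = pos[3 * k] - pos[3 * j], vy = pos[3 * k + 1] - pos[3 * j + 1],
           vz = pos[3 * k + 2] - pos[3 * j + 2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double d = c - c0;
    E.angle += kf * d * d;
    double pre = 2.0 * kf * d;
    double gi_x = pre * (vx / (nu * nv) - c * ux / (nu * nu));
    double gi_y = pre * (vy / (nu * nv) - c * uy / (nu * nu));
    double gi_z = pre * (vz / (nu * nv) - c * uz / (nu * nu));
    double gk_x = pre * (ux / (nu * nv) - c * vx / (nv * nv));
    double gk_y = pre * (uy / (nu * nv) - c * vy / (nv * nv));
    double gk_z = pre * (uz / (nu * nv) - c * vz / (nv * nv));
    frc[3 * i] -= gi_x; frc[3 * i + 1] -= gi_y; frc[3 * i + 2] -= gi_z;
    frc[3 * k] -= gk_x; frc[3 * k + 1] -= gk_y; frc[3 * k + 2] -= gk_z;
    frc[3 * j] += gi_x + gk_x;
    frc[3 * j + 1] += gi_y + gk_y;
    frc[3 * j + 2] += gi_z + gk_z;
  }

  // dihedrals: E = k (1 + cos(m phi - phis))
  for (int d = 0; d < S.dihedrals.nrow(); ++d) {
    int i = (int)S.dihedrals(d, 0), j = (int)S.dihedrals(d, 1),
        k = (int)S.dihedrals(d, 2), l = (int)S.dihedrals(d, 3);
    double phis = S.dihedrals(d, 4), kf = S.dihedrals(d, 5),
           m = S.dihedrals(d, 6);
    double b1[3] = {pos[3 * j] - pos[3 * i], pos[3 * j + 1] - pos[3 * i + 1],
                    pos[3 * j + 2] - pos[3 * i + 2]};
    double b2[3] = {pos[3 * k] - pos[3 * j], pos[3 * k + 1] - pos[3 * j + 1],
                    pos[3 * k + 2] - pos[3 * j + 2]};
    double b3[3] = {pos[3 * l] - pos[3 * k], pos[3 * l + 1] - pos[3 * k + 1],
                    pos[3 * l + 2] - pos[3 * k + 2]};
    double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                    b1[2] * b2[0] - b1[0] * b2[2],
                    b1[0] * b2[1] - b1[1] * b2[0]};
    double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                    b2[2] * b3[0] - b2[0] * b3[2],
                    b2[0] * b3[1] - b2[1] * b3[0]};
    double n1sq = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
    double n2sq = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
    double b2n = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    if (n1sq < 1e-12 || n2sq < 1e-12) continue; // collinear: undefined, skip
    double cx[3] = {n1[1] * n2[2] - n1[2] * n2[1],
                    n1[2] * n2[0] - n1[0] * n2[2],
                    n1[0] * n2[1] - n1[1] * n2[0]};
    double sy = (cx[0] * b2[0] + cx[1] * b2[1] + cx[2] * b2[2]) / b2n;
    double cphi = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double phi = std::atan2(sy, cphi);
    E.dihedral += kf * (1.0 + std::cos(m * phi - phis));
    double p = -kf * m * std::sin(m * phi - phis); // dE/dphi
    double fi_[3], fl_[3];
    // grad phi: g_i = -(|b2|/|n1|^2) n1, g_l = +(|b2|/|n2|^2) n2,
    // g_j = -(1+s) g_i + t g_l, g_k = s g_i - (1+t) g_l; F = -p grad phi
    for (int c = 0; c < 3; ++c) {
      fi_[c] = p * (b2n / n1sq) * n1[c];
      fl_[c] = -p * (b2n / n2sq) * n2[c];
    }
    double sdot = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (b2n * b2n);
    double tdot = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (b2n * b2n);
    for (int c = 0; c < 3; ++c) {
      double fj_ = -fi_[c] - sdot * fi_[c] + tdot * fl_[c];
      double fk_ = -fl_[c] + sdot * fi_[c] - tdot * fl_[c];
      frc[3 * i + c] += fi_[c];
      frc[3 * j + c] += fj_;
      frc[3 * k + c] += fk_;
      frc[3 * l + c] += fl_[c];
    }
  }

  // per-axis harmonic positional restraints: E = k (x - x0)^2
  if (S.restraints.nrow() == n) {
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 3; ++c) {
        double k = S.restraints(i, c);
        if (k != 0.0) {
          double dd = pos[3 * i + c] - S.restraints(i, 3 + c);
          E.restraint += k * dd * dd;
          frc[3 * i + c] -= 2.0 * k * dd;
        }
      }
    }
  }

  return E;
}

// [[Rcpp::export(name = ".cg_energy_cpp")]]
List cg_energy_cpp(List sys, NumericMatrix xyz) {
  System S = build_system(sys);
  if (xyz.nrow() != S.n) stop("coordinate/bead count mismatch");
  std::vector<double> pos(3 * S.n), frc(3 * S.n), pb(S.n, 0.0);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) pos[3 * i + c] = xyz(i, c);
  Energies E = compute(S, pos, frc, &pb);
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) F(i, c) = frc[3 * i + c];
  return List::create(
      _["total"] = E.total(),
      _["terms"] = NumericVector::create(
          _["bond"] = E.bond, _["angle"] = E.angle,
          _["dihedral"] = E.dihedral, _["lj"] = E.lj, _["elec"] = E.elec,
          _["solvation"] = E.solv, _["restraint"] = E.restraint),
      _["per_bead_solvation"] = NumericVector(pb.begin(), pb.end()),
      _["forces"] = F);
}

// [[Rcpp::export(name = ".cg_switching_cpp")]]
NumericVector cg_switching_cpp(NumericVector z, double thickness, double nexp) {
  Membrane m; m.on = true; m.T = thickness; m.nexp = nexp; m.a = 0.85;
  NumericVector out(z.size());
  for (int i = 0; i < z.size(); ++i) out[i] = fswitch(z[i], m);
  return out;
}

// BAOAB Langevin propagator; gamma in 1/fs, dt in fs, temp in K.
// Random numbers come from R's RNG so set.seed() controls the trajectory.
// [[Rcpp::export(name = ".cg_langevin_cpp")]]
List cg_langevin_cpp(List sys, NumericMatrix xyz, NumericMatrix vel0,
                     double dt, double gamma, double temp, int nsteps,
                     int stride, bool save_vel) {
  System S = build_system(sys);
  const int n = S.n;
  std::vector<double> pos(3 * n), v(3 * n), frc(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      pos[3 * i + c] = xyz(i, c);
      v[3 * i + c] = vel0(i, c);
    }
  double c1 = std::exp(-gamma * dt);
  std::vector<double> c2(n), hdtm(n);
  for (int i = 0; i < n; ++i) {
    c2[i] = std::sqrt((1.0 - c1 * c1) * KB * temp * FCONV / S.mass[i]);
    hdtm[i] = 0.5 * dt * FCONV / S.mass[i];
  }
  int nsave = nsteps / stride;
  NumericMatrix frames(nsave, 3 * n);
  NumericMatrix vels(save_vel ? nsave : 1, save_vel ? 3 * n : 1);
  NumericVector times(nsave), ekin(nsave), epot(nsave);
  Energies E = compute(S, pos, frc);
  int isave = 0, blow_step = -1;
  RNGScope rng;
  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] += hdtm[i] * frc[3 * i + c];
    for (size_t k = 0; k < pos.size(); ++k) pos[k] += 0.5 * dt * v[k];
    if (gamma > 0.0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          v[3 * i + c] = c1 * v[3 * i + c] + c2[i] * norm_rand();
    }
    for (size_t k = 0; k < pos.size(); ++k) pos[k] += 0.5 * dt * v[k];
    E = compute(S, pos, frc, nullptr, false);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] += hdtm[i] * frc[3 * i + c];
    bool bad = !std::isfinite(E.total());
    for (size_t k = 0; k < pos.size() && !bad; ++k)
      if (!std::isfinite(pos[k]) || std::fabs(pos[k]) > 1e6) bad = true;
    if (bad) { blow_step = step; break; }
    if (step % stride == 0 && isave < nsave) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        double vv = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                    v[3 * i + 2] * v[3 * i + 2];
        ke += 0.5 * S.mass[i] * vv / FCONV;
      }
      for (int k = 0; k < 3 * n; ++k) frames(isave, k) = pos[k];
      if (save_vel)
        for (int k = 0; k < 3 * n; ++k) vels(isave, k) = v[k];
      times[isave] = step * dt;
      ekin[isave] = ke;
      epot[isave] = E.total();
      ++isave;
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix xyz_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      xyz_out(i, c) = pos[3 * i + c];
      vel_out(i, c) = v[3 * i + c];
    }
  return List::create(_["frames"] = frames, _["velocities"] = vels,
                      _["times"] = times, _["kinetic"] = ekin,
                      _["potential"] = epot, _["n_saved"] = isave,
                      _["xyz"] = xyz_out, _["vel"] = vel_out,
                      _["blow_step"] = blow_step);
}

// steepest descent with adaptive step and backtracking
// [[Rcpp::export(name = ".cg_minimize_cpp")]]
List cg_minimize_cpp(List sys, NumericMatrix xyz, int maxit, double ftol,
                     double step0) {
  System S = build_system(sys);
  const int n = S.n;
  std::vector<double> pos(3 * n), frc(3 * n), trial(3 * n), tfrc(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) pos[3 * i + c] = xyz(i, c);
  Energies E = compute(S, pos, frc, nullptr, false);
  double e = E.total(), step = step0;
  int it = 0;
  for (; it < maxit; ++it) {
    double fmax = 0.0;
    for (double f : frc) fmax = std::max(fmax, std::fabs(f));
    if (!std::isfinite(e)) stop("non-finite energy during minimization");
    if (fmax < ftol) break;
    double scale = step / std::max(fmax, 1e-12);
    for (size_t k = 0; k < pos.size(); ++k)
      trial[k] = pos[k] + scale * frc[k];
    Energies Et = compute(S, trial, tfrc, nullptr, false);
    if (std::isfinite(Et.total()) && Et.total() <= e) {
      pos.swap(trial); frc.swap(tfrc); e = Et.total();
      step = std::min(step * 1.2, 1.0);
    } else {
      step *= 0.5;
      if (step < 1e-10) break;
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = pos[3 * i + c];
  return List::create(_["xyz"] = out, _["energy"] = e, _["iterations"] = it);
}
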