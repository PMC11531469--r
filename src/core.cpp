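// Core numerical kernels: potential-energy terms with analytic forces,
// the BAOAB Langevin integrator, and trajectory contact counting.
// Units: length A, energy kcal/mol, mass amu; with these, the intrinsic
// time unit is sqrt(amu*A^2*mol/kcal) = 48.89 fs and no unit conversion
// factors appear in the equations of motion.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

struct PairKey {
  static inline long long key(int i, int j, int n) {
    if (i > j) std::swap(i, j);
    return (long long)i * n + j;
  }
};

struct System {
  int n;
  // bonded terms (0-based indices)
  std::vector<int> b_i, b_j;            std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;       std::vector<double> a_t0, a_kt;
  std::vector<int> d_i, d_j, d_k, d_l;  std::vector<double> d_p0, d_kp;
  // native contacts (eps_eff already includes the global sigma of its set)
  std::vector<int> c_i, c_j, c_lab;     std::vector<double> c_r0, c_eps;
  int n_labels;
  // nonbonded parameters
  std::vector<double> q_dna, q_pro, radius;
  std::vector<int> is_dna;
  double eps_ev;
  double ke_eps;        // Coulomb constant / dielectric, kcal*A/(mol*e^2)
  double kappa;         // 1/Debye length, 1/A
  double elec_cutoff;   // A; R_PosInf disables truncation (no shift)
  std::unordered_set<long long> excl_nb;  // 1-2 and 1-3: no EV, no elec
  std::unordered_set<long long> excl_ev;  // contact pairs: no EV
  // restraints and confinement
  std::vector<int> r_i; std::vector<double> r_x, r_y, r_z, r_k;
  double conf_R, conf_k, conf_c[3];
  std::vector<double> mass;
};

static System parse_system(const List& sys) {
  System S;
  S.n = as<int>(sys["n"]);
  NumericMatrix B = sys["bonds"], A = sys["angles"], D = sys["dihedrals"],
    C = sys["contacts"], R = sys["restraints"];
  for (int r = 0; r < B.nrow(); ++r) {
    S.b_i.push_back((int)B(r,0)-1); S.b_j.push_back((int)B(r,1)-1);
    S.b_r0.push_back(B(r,2)); S.b_k.push_back(B(r,3));
  }
  for (int r = 0; r < A.nrow(); ++r) {
    S.a_i.push_back((int)A(r,0)-1); S.a_j.push_back((int)A(r,1)-1);
    S.a_k.push_back((int)A(r,2)-1); S.a_t0.push_back(A(r,3)); S.a_kt.push_back(A(r,4));
  }
  for (int r = 0; r < D.nrow(); ++r) {
    S.d_i.push_back((int)D(r,0)-1); S.d_j.push_back((int)D(r,1)-1);
    S.d_k.push_back((int)D(r,2)-1); S.d_l.push_back((int)D(r,3)-1);
    S.d_p0.push_back(D(r,4)); S.d_kp.push_back(D(r,5));
  }
  for (int r = 0; r < C.nrow(); ++r) {
    S.c_i.push_back((int)C(r,0)-1); S.c_j.push_back((int)C(r,1)-1);
    S.c_r0.push_back(C(r,2)); S.c_eps.push_back(C(r,3));
    S.c_lab.push_back((int)C(r,4)-1);
  }
  S.n_labels = as<int>(sys["n_labels"]);
  S.q_dna = as<std::vector<double> >(sys["q_dna"]);
  S.q_pro = as<std::vector<double> >(sys["q_pro"]);
  S.radius = as<std::vector<double> >(sys["radius"]);
  S.is_dna = as<std::vector<int> >(sys["is_dna"]);
  S.eps_ev = as<double>(sys["eps_ev"]);
  S.ke_eps = as<double>(sys["ke_eps"]);
  S.kappa = as<double>(sys["kappa"]);
  S.elec_cutoff = as<double>(sys["elec_cutoff"]);
  IntegerMatrix EN = sys["excl_nb"], EV = sys["excl_ev"];
  for (int r = 0; r < EN.nrow(); ++r)
    S.excl_nb.insert(PairKey::key(EN(r,0)-1, EN(r,1)-1, S.n));
  for (int r = 0; r < EV.nrow(); ++r)
    S.excl_ev.insert(PairKey::key(EV(r,0)-1, EV(r,1)-1, S.n));
  for (int r = 0; r < R.nrow(); ++r) {
    S.r_i.push_back((int)R(r,0)-1);
    S.r_x.push_back(R(r,1)); S.r_y.push_back(R(r,2)); S.r_z.push_back(R(r,3));
    S.r_k.push_back(R(r,4));
  }
  List conf = sys["confinement"];
  S.conf_R = as<double>(conf["radius"]); S.conf_k = as<double>(conf["k"]);
  NumericVector cc = conf["center"];
  S.conf_c[0] = cc[0]; S.conf_c[1] = cc[1]; S.conf_c[2] = cc[2];
  S.mass = as<std::vector<double> >(sys["mass"]);
  return S;
}

struct Breakdown {
  double bond = 0, angle = 0, dihedral = 0, ev = 0, elec = 0,
    restraint = 0, confine = 0;
  std::vector<double> go;  // per contact-set label
};

// Energy and forces for coordinates x (layout x[3*i + k]); forces are the
// exact negative gradient of every term.
static Breakdown energy_forces(const System& S, const double* x, double* f) {
  Breakdown E; E.go.assign(S.n_labels, 0.0);
  std::fill(f, f + 3 * S.n, 0.0);

  for (size_t t = 0; t < S.b_i.size(); ++t) {
    int i = S.b_i[t], j = S.b_j[t];
    double d[3], r2 = 0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - x[3*j+k]; r2 += d[k]*d[k]; }
    double r = std::sqrt(r2), dr = r - S.b_r0[t];
    E.bond += S.b_k[t] * dr * dr;
    double c = -2.0 * S.b_k[t] * dr / r;
    for (int k = 0; k < 3; ++k) { f[3*i+k] += c * d[k]; f[3*j+k] -= c * d[k]; }
  }

  for (size_t t = 0; t < S.a_i.size(); ++t) {
    int i = S.a_i[t], j = S.a_j[t], kk = S.a_k[t];
    double rij[3], rkj[3], nij = 0, nkj = 0, dot = 0;
    for (int k = 0; k < 3; ++k) {
      rij[k] = x[3*i+k] - x[3*j+k]; rkj[k] = x[3*kk+k] - x[3*j+k];
      nij += rij[k]*rij[k]; nkj += rkj[k]*rkj[k]; dot += rij[k]*rkj[k];
    }
    nij = std::sqrt(nij); nkj = std::sqrt(nkj);
    double ct = dot / (nij * nkj);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct), dth = th - S.a_t0[t];
    E.angle += S.a_kt[t] * dth * dth;
    double st = std::sqrt(std::max(1e-12, 1.0 - ct*ct));
    double pref = 2.0 * S.a_kt[t] * dth / st;  // -dV/dtheta * (-1/sin) chain
    for (int k = 0; k < 3; ++k) {
      double gi = (rkj[k]/(nij*nkj) - ct*rij[k]/(nij*nij));
      double gk = (rij[k]/(nij*nkj) - ct*rkj[k]/(nkj*nkj));
      f[3*i+k]  += pref * gi;
      f[3*kk+k] += pref * gk;
      f[3*j+k]  -= pref * (gi + gk);
    }
  }

  for (size_t t = 0; t < S.d_i.size(); ++t) {
    int i = S.d_i[t], j = S.d_j[t], kk = S.d_k[t], l = S.d_l[t];
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = x[3*j+k] - x[3*i+k];
      b2[k] = x[3*kk+k] - x[3*j+k];
      b3[k] = x[3*l+k] - x[3*kk+k];
    }
    double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0] };
    double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0] };
    double n1n = std::sqrt(n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2]);
    double n2n = std::sqrt(n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2]);
    double b2n = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1n < 1e-9 || n2n < 1e-9) continue;
    double m1[3] = { n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2], n1[0]*b2[1]-n1[1]*b2[0] };
    double xphi = 0, yphi = 0;
    for (int k = 0; k < 3; ++k) { xphi += n1[k]*n2[k]; yphi += m1[k]*n2[k]/b2n; }
    double phi = std::atan2(yphi, xphi);
    double dphi = phi - S.d_p0[t];
    E.dihedral += S.d_kp[t] * (1.0 - std::cos(dphi));
    double dV = S.d_kp[t] * std::sin(dphi);   // dV/dphi
    // standard analytic dihedral gradient
    double fi[3], fl[3];
    for (int k = 0; k < 3; ++k) {
      fi[k] = -dV * b2n / (n1n*n1n) * n1[k];
      fl[k] =  dV * b2n / (n2n*n2n) * n2[k];
    }
    double b1b2 = 0, b3b2 = 0;
    for (int k = 0; k < 3; ++k) { b1b2 += b1[k]*b2[k]; b3b2 += b3[k]*b2[k]; }
    double s1 = b1b2 / (b2n*b2n), s2 = b3b2 / (b2n*b2n);
    for (int k = 0; k < 3; ++k) {
      double fj = -fi[k] - s1*fi[k] + s2*fl[k];
      double fk = -fl[k] + s1*fi[k] - s2*fl[k];
      f[3*i+k] += fi[k]; f[3*j+k] += fj; f[3*kk+k] += fk; f[3*l+k] += fl[k];
    }
  }

  for (size_t t = 0; t < S.c_i.size(); ++t) {
    int i = S.c_i[t], j = S.c_j[t];
    double d[3], r2 = 0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - x[3*j+k]; r2 += d[k]*d[k]; }
    double r = std::sqrt(r2);
    if (r <= 0) stop("zero distance in native-contact pair");
    double s = S.c_r0[t] / r;
    double s2 = s*s, s4 = s2*s2, s10 = s4*s4*s2, s12 = s10*s2;
    E.go[S.c_lab[t]] += S.c_eps[t] * (5.0*s12 - 6.0*s10);
    // dV/dr = eps*(-60 s^12 + 60 s^10)/r ; force = -dV/dr * d/r
    double dV = S.c_eps[t] * 60.0 * (s10 - s12) / r;
    double c = -dV / r;
    for (int k = 0; k < 3; ++k) { f[3*i+k] += c * d[k]; f[3*j+k] -= c * d[k]; }
  }

  // nonbonded: all pairs
  double rc = S.elec_cutoff, rc2 = std::isfinite(rc) ? rc*rc : R_PosInf;
  for (int i = 0; i < S.n - 1; ++i) {
    for (int j = i + 1; j < S.n; ++j) {
      long long key = PairKey::key(i, j, S.n);
      if (S.excl_nb.count(key)) continue;
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - x[3*j+k]; r2 += d[k]*d[k]; }
      double dij = S.radius[i] + S.radius[j];
      bool do_ev = r2 < dij*dij && !S.excl_ev.count(key);
      double qq = 0;
      if (r2 < rc2) {
        // partner-class-dependent charge: a bead exposes its DNA-context
        // charge to DNA partners and its protein-context charge otherwise
        double qi = S.is_dna[j] ? S.q_dna[i] : S.q_pro[i];
        double qj = S.is_dna[i] ? S.q_dna[j] : S.q_pro[j];
        qq = qi * qj;
      }
      if (!do_ev && qq == 0) continue;
      double r = std::sqrt(r2);
      if (r <= 0) stop("zero distance between beads %d and %d", i + 1, j + 1);
      double dV = 0;
      if (do_ev) {
        double s = dij / r, s2 = s*s, s6 = s2*s2*s2, s12 = s6*s6;
        E.ev += S.eps_ev * (s12 - 1.0);
        dV += -12.0 * S.eps_ev * s12 / r;
      }
      if (qq != 0) {
        double u = S.ke_eps * qq * std::exp(-S.kappa * r) / r;
        double ushift = 0;
        if (std::isfinite(rc))
          ushift = S.ke_eps * qq * std::exp(-S.kappa * rc) / rc;
        E.elec += u - ushift;
        dV += -u * (S.kappa + 1.0/r);
      }
      double c = -dV / r;
      for (int k = 0; k < 3; ++k) { f[3*i+k] += c * d[k]; f[3*j+k] -= c * d[k]; }
    }
  }

  for (size_t t = 0; t < S.r_i.size(); ++t) {
    int i = S.r_i[t];
    double d[3] = { x[3*i] - S.r_x[t], x[3*i+1] - S.r_y[t], x[3*i+2] - S.r_z[t] };
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    E.restraint += S.r_k[t] * r2;
    for (int k = 0; k < 3; ++k) f[3*i+k] -= 2.0 * S.r_k[t] * d[k];
  }

  if (S.conf_R > 0) {
    for (int i = 0; i < S.n; ++i) {
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - S.conf_c[k]; r2 += d[k]*d[k]; }
      double r = std::sqrt(r2);
      if (r > S.conf_R) {
        double dr = r - S.conf_R;
        E.confine += S.conf_k * dr * dr;
        double c = -2.0 * S.conf_k * dr / r;
        for (int k = 0; k < 3; ++k) f[3*i+k] += c * d[k];
      }
    }
  }
  return E;
}

static List breakdown_to_list(const Breakdown& E) {
  double go_total = 0;
  NumericVector go(E.go.size());
  for (size_t i = 0; i < E.go.size(); ++i) { go[i] = E.go[i]; go_total += E.go[i]; }
  double total = E.bond + E.angle + E.dihedral + go_total + E.ev + E.elec +
    E.restraint + E.confine;
  return List::create(
    _["bond"] = E.bond, _["angle"] = E.angle, _["dihedral"] = E.dihedral,
    _["go"] = go, _["excluded_volume"] = E.ev, _["electrostatic"] = E.elec,
    _["restraint"] = E.restraint, _["confinement"] = E.confine,
    _["total"] = total);
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, List sys) {
  System S = parse_system(sys);
  if (coords.nrow() != S.n) stop("coordinate/bead count mismatch");
  std::vector<double> x(3 * S.n), f(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords(i, k);
  Breakdown E = energy_forces(S, x.data(), f.data());
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = f[3*i+k];
  List out = breakdown_to_list(E);
  out["forces"] = F;
  return out;
}

// BAOAB Langevin integrator. kT in kcal/mol, gamma in inverse time units,
// dt in time units. Returns saved frames (n_saved x n x 3), per-save
// potential/kinetic energies and the final phase-space point.
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix coords, Nullable<NumericMatrix> vels, List sys,
                  int n_steps, double dt, double kT, double gamma,
                  int save_every, double seed) {
  System S = parse_system(sys);
  int n = S.n;
  if (coords.nrow() != n) stop("coordinate/bead count mismatch");
  std::vector<double> x(3*n), v(3*n), f(3*n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords(i, k);
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  if (vels.isNotNull()) {
    NumericMatrix V(vels);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3*i+k] = V(i, k);
  } else {
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(kT / S.mass[i]);
      for (int k = 0; k < 3; ++k) v[3*i+k] = s * gauss(rng);
    }
  }
  double c1 = std::exp(-gamma * dt), c2 = std::sqrt(1.0 - c1 * c1);
  Breakdown E = energy_forces(S, x.data(), f.data());

  int n_saved = n_steps / save_every;
  NumericVector frames((R_xlen_t)n_saved * n * 3);
  NumericVector epot(n_saved), ekin(n_saved);
  IntegerVector steps(n_saved);
  bool diverged = false;
  int isave = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double hdt = 0.5 * dt / S.mass[i];
      for (int k = 0; k < 3; ++k) v[3*i+k] += hdt * f[3*i+k];
    }
    for (int q = 0; q < 3*n; ++q) x[q] += 0.5 * dt * v[q];
    for (int i = 0; i < n; ++i) {
      double s = c2 * std::sqrt(kT / S.mass[i]);
      for (int k = 0; k < 3; ++k) v[3*i+k] = c1 * v[3*i+k] + s * gauss(rng);
    }
    for (int q = 0; q < 3*n; ++q) x[q] += 0.5 * dt * v[q];
    E = energy_forces(S, x.data(), f.data());
    for (int i = 0; i < n; ++i) {
      double hdt = 0.5 * dt / S.mass[i];
      for (int k = 0; k < 3; ++k) v[3*i+k] += hdt * f[3*i+k];
    }
    if (step % save_every == 0) {
      double ep = E.bond + E.angle + E.dihedral + E.ev + E.elec +
        E.restraint + E.confine;
      for (size_t q = 0; q < E.go.size(); ++q) ep += E.go[q];
      double ek = 0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) ek += 0.5 * S.mass[i] * v[3*i+k]*v[3*i+k];
      if (!std::isfinite(ep) || std::fabs(ep) > 1e9) { diverged = true; break; }
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[isave + (R_xlen_t)n_saved * (i + (R_xlen_t)n * k)] = x[3*i+k];
      epot[isave] = ep; ekin[isave] = ek; steps[isave] = step;
      ++isave;
    }
  }
  if (isave < n_saved) {  // divergence: truncate to last stable frame
    if (isave == 0) {
      frames = NumericVector(0);
      epot = NumericVector(0); ekin = NumericVector(0);
      steps = IntegerVector(0);
    } else {
      NumericVector fr2((R_xlen_t)isave * n * 3);
      for (int s = 0; s < isave; ++s)
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < 3; ++k)
            fr2[s + (R_xlen_t)isave * (i + (R_xlen_t)n * k)] =
              frames[s + (R_xlen_t)n_saved * (i + (R_xlen_t)n * k)];
      frames = fr2;
      epot = epot[Range(0, isave - 1)];
      ekin = ekin[Range(0, isave - 1)];
      steps = steps[Range(0, isave - 1)];
    }
    n_saved = isave;
  }
  frames.attr("dim") = IntegerVector::create(n_saved, n, 3);
  NumericMatrix Xl(n, 3), Vl(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { Xl(i,k) = x[3*i+k]; Vl(i,k) = v[3*i+k]; }
  return List::create(_["frames"] = frames, _["step_ids"] = steps,
                      _["epot"] = epot, _["ekin"] = ekin,
                      _["coords_last"] = Xl, _["vels_last"] = Vl,
                      _["diverged"] = diverged);
}

// Per-frame count of group-a beads having any group-b bead within cutoff.
// frames: array (n_frames x n x 3); ia, ib: 1-based bead indices.
// [[Rcpp::export]]
IntegerVector cpp_contact_count(NumericVector frames, IntegerVector ia,
                                IntegerVector ib, double cutoff) {
  IntegerVector dim = frames.attr("dim");
  int nf = dim[0], n = dim[1];
  double c2 = cutoff * cutoff;
  IntegerVector out(nf);
  for (int fidx = 0; fidx < nf; ++fidx) {
    int count = 0;
    for (int a = 0; a < ia.size(); ++a) {
      int i = ia[a] - 1;
      double xi[3];
      for (int k = 0; k < 3; ++k)
        xi[k] = frames[fidx + (R_xlen_t)nf * (i + (R_xlen_t)n * k)];
      for (int b = 0; b < ib.size(); ++b) {
        int j = ib[b] - 1;
        double r2 = 0;
        for (int k = 0; k < 3; ++k) {
          double d = xi[k] - frames[fidx + (R_xlen_t)nf * (j + (R_xlen_t)n * k)];
          r2 += d * d;
        }
        if (r2 < c2) { ++count; break; }
      }
    }
    out[fidx] = count;
  }
  return out;
}

// Per-frame, per-a-bead contact indicator (n_frames x length(ia)).
// [[Rcpp::export]]
LogicalMatrix cpp_contact_flags(NumericVector frames, IntegerVector ia,
                                IntegerVector ib, double cutoff) {
  IntegerVector dim = frames.attr("dim");
  int nf = dim[0], n = dim[1];
  double c2 = cutoff * cutoff;
  LogicalMatrix out(nf, ia.size());
  for (int fidx = 0; fidx < nf; ++fidx) {
    for (int a = 0; a < ia.size(); ++a) {
      int i = ia[a] - 1;
      double xi[3];
      for (int k = 0; k < 3; ++k)
        xi[k] = frames[fidx + (R_xlen_t)nf * (i + (R_xlen_t)n * k)];
      bool hit = false;
      for (int b = 0; b < ib.size() && !hit; ++b) {
        int j = ib[b] - 1;
        double r2 = 0;
        for (int k = 0; k < 3; ++k) {
          double d = xi[k] - frames[fidx + (R_xlen_t)nf * (j + (R_xlen_t)n * k)];
          r2 += d * d;
        }
        hit = r2 < c2;
      }
      out(fidx, a) = hit;
    }
  }
  return out;
}

// Per-frame minimum distance between two bead groups.
// [[Rcpp::export]]
NumericVector cpp_min_distance(NumericVector frames, IntegerVector ia,
                               IntegerVector ib) {
  IntegerVector dim = frames.attr("dim");
  int nf = dim[0], n = dim[1];
  NumericVector out(nf);
  for (int fidx = 0; fidx < nf; ++fidx) {
    double best = R_PosInf;
    for (int a = 0; a < ia.size(); ++a) {
      int i = ia[a] - 1;
      double xi[3];
      for (int k = 0; k < 3; ++k)
        xi[k] = frames[fidx + (R_xlen_t)nf * (i + (R_xlen_t)n * k)];
      for (int b = 0; b < ib.size(); ++b) {
        int j = ib[b] - 1;
        double r2 = 0;
        for (int k = 0; k < 3; ++k) {
          double d = xi[k] - frames[fidx + (R_xlen_t)nf * (j + (R_xlen_t)n * k)];
          r2 += d * d;
        }
        if (r2 < best) best = r2;
      }
    }
    out[fidx] = std::sqrt(best);
  }
  return out;
}
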