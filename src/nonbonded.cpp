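#include <Rcpp.h>
using namespace Rcpp;

// Coulomb + Lennard-Jones pair interactions.
// Units: kcal/mol, Angstrom, elementary charges.
// LJ form: eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6) with
// eps_ij = sqrt(eps_i * eps_j), Rmin_ij = rmin_half_i + rmin_half_j.
// Optional CHARMM-style potential switching between r_on and the cutoff
// keeps energy and force continuous at the cutoff.

static const double R_OVERLAP = 1e-6;

struct SwitchFn {
  bool on;
  double ron2, roff2, denom;
  SwitchFn(bool use, double ron, double roff) : on(use) {
    ron2 = ron * ron;
    roff2 = roff * roff;
    double d = roff2 - ron2;
    denom = d * d * d;
  }
  // value and radial derivative of the switching function at r
  inline void eval(double r, double r2, double &s, double &dsdr) const {
    if (!on || r2 <= ron2) { s = 1.0; dsdr = 0.0; return; }
    double a = roff2 - r2;
    s = a * a * (roff2 + 2.0 * r2 - 3.0 * ron2) / denom;
    dsdr = 12.0 * r * a * (ron2 - r2) / denom;
  }
};

// pairwise energy/force between one atom pair; returns energies via refs,
// force magnitude dE/dr via ref (force on i is -(dE/dr) * rhat_ij)
static inline void pair_terms(double r, double r2, double qi, double qj,
                              double epsij, double rminij, double kc,
                              double diel, const SwitchFn &sw,
                              double &eel, double &evdw, double &dedr) {
  double s, dsdr;
  sw.eval(r, r2, s, dsdr);
  double eel0 = kc * qi * qj / (diel * r);
  double sr = rminij / r;
  double sr2 = sr * sr;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double evdw0 = epsij * (sr12 - 2.0 * sr6);
  double deel0 = -eel0 / r;
  double devdw0 = epsij * 12.0 * (sr6 - sr12) / r;
  eel = eel0 * s;
  evdw = evdw0 * s;
  dedr = (deel0 + devdw0) * s + (eel0 + evdw0) * dsdr;
}

// [[Rcpp::export]]
List nb_cross_cpp(NumericMatrix xa, NumericMatrix xb,
                  NumericVector qa, NumericVector qb,
                  NumericVector ea, NumericVector eb,
                  NumericVector ra, NumericVector rb,
                  double kc, double diel, double cutoff,
                  bool use_switch, double r_on, bool want_forces) {
  int na = xa.nrow(), nb = xb.nrow();
  bool use_cut = cutoff > 0;
  double cut2 = cutoff * cutoff;
  SwitchFn sw(use_switch && use_cut, r_on, cutoff);
  double elec = 0.0, vdw = 0.0;
  NumericMatrix fa(want_forces ? na : 1, 3);
  for (int i = 0; i < na; ++i) {
    double xi = xa(i, 0), yi = xa(i, 1), zi = xa(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = xi - xb(j, 0), dy = yi - xb(j, 1), dz = zi - xb(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (use_cut && r2 > cut2) continue;
      double r = std::sqrt(r2);
      if (r < R_OVERLAP)
        stop("overlapping atoms: pair (%d, %d) at r = %g Angstrom", i + 1,
             j + 1, r);
      double eel, evdw, dedr;
      pair_terms(r, r2, qa[i], qb[j], std::sqrt(ea[i] * eb[j]),
                 ra[i] + rb[j], kc, diel, sw, eel, evdw, dedr);
      elec += eel;
      vdw += evdw;
      if (want_forces) {
        double fscale = -dedr / r; // force on i along (xi - xj)
        fa(i, 0) += fscale * dx;
        fa(i, 1) += fscale * dy;
        fa(i, 2) += fscale * dz;
      }
    }
  }
  return List::create(_["elec"] = elec, _["vdw"] = vdw, _["forces"] = fa);
}

// per-B-atom decomposition of the cross energy (used for residue-wise sums)
// [[Rcpp::export]]
List nb_per_atom_b_cpp(NumericMatrix xa, NumericMatrix xb,
                       NumericVector qa, NumericVector qb,
                       NumericVector ea, NumericVector eb,
                       NumericVector ra, NumericVector rb,
                       double kc, double diel, double cutoff,
                       bool use_switch, double r_on) {
  int na = xa.nrow(), nb = xb.nrow();
  bool use_cut = cutoff > 0;
  double cut2 = cutoff * cutoff;
  SwitchFn sw(use_switch && use_cut, r_on, cutoff);
  NumericVector elec(nb), vdw(nb), mind(nb);
  std::fill(mind.begin(), mind.end(), R_PosInf);
  for (int j = 0; j < nb; ++j) {
    double xj = xb(j, 0), yj = xb(j, 1), zj = xb(j, 2);
    for (int i = 0; i < na; ++i) {
      double dx = xa(i, 0) - xj, dy = xa(i, 1) - yj, dz = xa(i, 2) - zj;
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r < mind[j]) mind[j] = r;
      if (use_cut && r2 > cut2) continue;
      if (r < R_OVERLAP)
        stop("overlapping atoms: pair (%d, %d) at r = %g Angstrom", i + 1,
             j + 1, r);
      double eel, evdw, dedr;
      pair_terms(r, r2, qa[i], qb[j], std::sqrt(ea[i] * eb[j]),
                 ra[i] + rb[j], kc, diel, sw, eel, evdw, dedr);
      elec[j] += eel;
      vdw[j] += evdw;
    }
  }
  return List::create(_["elec"] = elec, _["vdw"] = vdw, _["min_dist"] = mind);
}

// probe-probe interactions: all atoms in one set, pairs within the same
// group (one rigid molecule) are excluded
// [[Rcpp::export]]
List nb_self_groups_cpp(NumericMatrix x, NumericVector q, NumericVector e,
                        NumericVector rh, IntegerVector group,
                        double kc, double diel, double cutoff,
                        bool use_switch, double r_on) {
  int n = x.nrow();
  bool use_cut = cutoff > 0;
  double cut2 = cutoff * cutoff;
  SwitchFn sw(use_switch && use_cut, r_on, cutoff);
  double elec = 0.0, vdw = 0.0;
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (group[i] == group[j]) continue;
      double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1),
             dz = x(i, 2) - x(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (use_cut && r2 > cut2) continue;
      double r = std::sqrt(r2);
      if (r < R_OVERLAP)
        stop("overlapping atoms: pair (%d, %d) at r = %g Angstrom", i + 1,
             j + 1, r);
      double eel, evdw, dedr;
      pair_terms(r, r2, q[i], q[j], std::sqrt(e[i] * e[j]), rh[i] + rh[j],
                 kc, diel, sw, eel, evdw, dedr);
      elec += eel;
      vdw += evdw;
      double fscale = -dedr / r;
      f(i, 0) += fscale * dx;
      f(i, 1) += fscale * dy;
      f(i, 2) += fscale * dz;
      f(j, 0) -= fscale * dx;
      f(j, 1) -= fscale * dy;
      f(j, 2) -= fscale * dz;
    }
  }
  return List::create(_["elec"] = elec, _["vdw"] = vdw, _["forces"] = f);
}

// minimum distance between two coordinate sets (contacts, occupancy)
// [[Rcpp::export]]
double min_dist_cpp(NumericMatrix xa, NumericMatrix xb) {
  double best = R_PosInf;
  for (int i = 0; i < xa.nrow(); ++i)
    for (int j = 0; j < xb.nrow(); ++j) {
      double dx = xa(i, 0) - xb(j, 0), dy = xa(i, 1) - xb(j, 1),
             dz = xa(i, 2) - xb(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
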