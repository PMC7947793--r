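// Intermolecular scoring (12-6 Lennard-Jones + Coulomb + flat-bottom AIRs)
// and rigid-body Metropolis Monte-Carlo refinement.  Uses R's RNG so runs
// are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double COULOMB = 332.0636;

struct FF {
  int nl, nr;
  const double *leps, *lsig, *lq, *reps, *rsig, *rq;
  double cutoff2;
  bool rdie;        // distance-dependent dielectric eps(r) = diel * r
  double diel;
};

// LJ (sigma form) + Coulomb over all intermolecular heavy-atom pairs within
// the cutoff.  lig/rec are column-major n x 3.
static void pair_energy(const double *lig, const double *rec, const FF &ff,
                        double &evdw, double &eelec) {
  evdw = 0.0; eelec = 0.0;
  const int nl = ff.nl, nr = ff.nr;
  for (int i = 0; i < nl; ++i) {
    const double xi = lig[i], yi = lig[i + nl], zi = lig[i + 2 * nl];
    const double ei = ff.leps[i], si = ff.lsig[i], qi = ff.lq[i];
    for (int j = 0; j < nr; ++j) {
      const double dx = xi - rec[j];
      const double dy = yi - rec[j + nr];
      const double dz = zi - rec[j + 2 * nr];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= ff.cutoff2) continue;
      const double sij = 0.5 * (si + ff.rsig[j]);
      const double eij = std::sqrt(ei * ff.reps[j]);
      const double s2 = sij * sij / d2;
      const double s6 = s2 * s2 * s2;
      evdw += 4.0 * eij * (s6 * s6 - s6);
      const double qq = qi * ff.rq[j];
      if (qq != 0.0) {
        if (ff.rdie) eelec += COULOMB * qq / (ff.diel * d2);
        else eelec += COULOMB * qq / (ff.diel * std::sqrt(d2));
      }
    }
  }
}

// Flat-bottom AIR energy; pair indices are 0-based, restraints delimited by
// air_len.  d_eff = (sum d^-6)^(-1/6).
static double air_energy(const double *lig, const double *rec, int nl, int nr,
                         const int *alig, const int *arec, const int *alen,
                         int n_air, const double *lower, const double *upper,
                         const double *kk) {
  double e = 0.0;
  int off = 0;
  for (int r = 0; r < n_air; ++r) {
    double s = 0.0;
    for (int p = 0; p < alen[r]; ++p) {
      const int i = alig[off + p], j = arec[off + p];
      const double dx = lig[i] - rec[j];
      const double dy = lig[i + nl] - rec[j + nr];
      const double dz = lig[i + 2 * nl] - rec[j + 2 * nr];
      const double d2 = dx * dx + dy * dy + dz * dz;
      s += 1.0 / (d2 * d2 * d2);
    }
    const double deff = std::pow(s, -1.0 / 6.0);
    double viol = 0.0;
    if (deff > upper[r]) viol = deff - upper[r];
    else if (deff < lower[r]) viol = lower[r] - deff;
    e += kk[r] * viol * viol;
    off += alen[r];
  }
  return e;
}

// [[Rcpp::export]]
List score_complex_cpp(NumericMatrix lig, NumericMatrix rec,
                       NumericVector leps, NumericVector lsig, NumericVector lq,
                       NumericVector reps, NumericVector rsig, NumericVector rq,
                       IntegerVector air_lig, IntegerVector air_rec,
                       IntegerVector air_len, NumericVector air_lower,
                       NumericVector air_upper, NumericVector air_k,
                       double cutoff, bool rdie, double diel) {
  FF ff = {static_cast<int>(lig.nrow()), static_cast<int>(rec.nrow()),
           leps.begin(), lsig.begin(), lq.begin(),
           reps.begin(), rsig.begin(), rq.begin(), cutoff * cutoff, rdie, diel};
  double evdw, eelec;
  pair_energy(lig.begin(), rec.begin(), ff, evdw, eelec);
  double eair = air_energy(lig.begin(), rec.begin(), ff.nl, ff.nr,
                           air_lig.begin(), air_rec.begin(), air_len.begin(),
                           air_len.size(), air_lower.begin(), air_upper.begin(),
                           air_k.begin());
  return List::create(_["E_vdw"] = evdw, _["E_elec"] = eelec, _["E_air"] = eair);
}

static void rotate_about(double *x, int n, const double R[9],
                         const double c[3]) {
  for (int i = 0; i < n; ++i) {
    const double px = x[i] - c[0], py = x[i + n] - c[1], pz = x[i + 2 * n] - c[2];
    x[i]         = R[0] * px + R[3] * py + R[6] * pz + c[0];
    x[i + n]     = R[1] * px + R[4] * py + R[7] * pz + c[1];
    x[i + 2 * n] = R[2] * px + R[5] * py + R[8] * pz + c[2];
  }
}

static void axis_angle_matrix(const double u[3], double th, double R[9]) {
  const double ct = std::cos(th), st = std::sin(th), omc = 1.0 - ct;
  R[0] = ct + u[0] * u[0] * omc;
  R[1] = u[1] * u[0] * omc + u[2] * st;
  R[2] = u[2] * u[0] * omc - u[1] * st;
  R[3] = u[0] * u[1] * omc - u[2] * st;
  R[4] = ct + u[1] * u[1] * omc;
  R[5] = u[2] * u[1] * omc + u[0] * st;
  R[6] = u[0] * u[2] * omc + u[1] * st;
  R[7] = u[1] * u[2] * omc - u[0] * st;
  R[8] = ct + u[2] * u[2] * omc;
}

// Metropolis Monte-Carlo over rigid rotations/translations of the ligand
// with a geometric cooling schedule; returns the lowest-total-energy pose
// visited (best-so-far bookkeeping).
// [[Rcpp::export]]
List mc_refine_cpp(NumericMatrix lig0, NumericMatrix rec,
                   NumericVector leps, NumericVector lsig, NumericVector lq,
                   NumericVector reps, NumericVector rsig, NumericVector rq,
                   IntegerVector air_lig, IntegerVector air_rec,
                   IntegerVector air_len, NumericVector air_lower,
                   NumericVector air_upper, NumericVector air_k,
                   double cutoff, bool rdie, double diel,
                   double w_vdw, double w_elec, double w_air,
                   int steps, double rot_step_deg, double trans_step,
                   double t_start, double t_end) {
  RNGScope scope;
  const int nl = lig0.nrow();
  FF ff = {nl, static_cast<int>(rec.nrow()),
           leps.begin(), lsig.begin(), lq.begin(),
           reps.begin(), rsig.begin(), rq.begin(), cutoff * cutoff, rdie, diel};
  std::vector<double> cur(lig0.begin(), lig0.begin() + 3 * nl);
  std::vector<double> prop(3 * nl), best(cur);

  double evdw, eelec, eair, etot;
  pair_energy(cur.data(), rec.begin(), ff, evdw, eelec);
  eair = air_energy(cur.data(), rec.begin(), ff.nl, ff.nr, air_lig.begin(),
                    air_rec.begin(), air_len.begin(), air_len.size(),
                    air_lower.begin(), air_upper.begin(), air_k.begin());
  etot = w_vdw * evdw + w_elec * eelec + w_air * eair;
  double best_terms[4] = {evdw, eelec, eair, etot};
  double cur_e = etot;

  const double rot_step = rot_step_deg * M_PI / 180.0;
  const double cool = (steps > 1) ? std::pow(t_end / t_start,
                                             1.0 / (steps - 1)) : 1.0;
  double temp = t_start;
  for (int s = 0; s < steps; ++s) {
    std::copy(cur.begin(), cur.end(), prop.begin());
    // random rotation about the current centroid
    double u[3] = {norm_rand(), norm_rand(), norm_rand()};
    double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    if (un < 1e-12) un = 1.0;
    u[0] /= un; u[1] /= un; u[2] /= un;
    const double th = norm_rand() * rot_step;
    double c[3] = {0.0, 0.0, 0.0};
    for (int i = 0; i < nl; ++i) {
      c[0] += prop[i]; c[1] += prop[i + nl]; c[2] += prop[i + 2 * nl];
    }
    c[0] /= nl; c[1] /= nl; c[2] /= nl;
    double R[9];
    axis_angle_matrix(u, th, R);
    rotate_about(prop.data(), nl, R, c);
    const double dt[3] = {norm_rand() * trans_step, norm_rand() * trans_step,
                          norm_rand() * trans_step};
    for (int i = 0; i < nl; ++i) {
      prop[i] += dt[0]; prop[i + nl] += dt[1]; prop[i + 2 * nl] += dt[2];
    }
    double pv, pe;
    pair_energy(prop.data(), rec.begin(), ff, pv, pe);
    const double pa = air_energy(prop.data(), rec.begin(), ff.nl, ff.nr,
                                 air_lig.begin(), air_rec.begin(),
                                 air_len.begin(), air_len.size(),
                                 air_lower.begin(), air_upper.begin(),
                                 air_k.begin());
    const double pt = w_vdw * pv + w_elec * pe + w_air * pa;
    if (pt <= cur_e || unif_rand() < std::exp(-(pt - cur_e) / temp)) {
      cur.swap(prop);
      cur_e = pt;
      if (pt < best_terms[3]) {
        best = cur;
        best_terms[0] = pv; best_terms[1] = pe; best_terms[2] = pa;
        best_terms[3] = pt;
      }
    }
    temp *= cool;
  }
  NumericMatrix out(nl, 3);
  std::copy(best.begin(), best.end(), out.begin());
  return List::create(_["coords"] = out,
                      _["E_vdw"] = best_terms[0], _["E_elec"] = best_terms[1],
                      _["E_air"] = best_terms[2], _["E_total"] = best_terms[3]);
}
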