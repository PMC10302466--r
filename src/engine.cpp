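#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Truncated-and-shifted Lennard-Jones pair interactions under the minimum
// image convention in an orthorhombic box. Pair parameters arrive as dense
// n_species x n_species matrices (Lorentz-Berthelot mixing is applied on the
// R side). Plain O(N^2) double loop over raw buffers: all systems here have
// N <~ 1500, where this beats cell-list bookkeeping.

static const double HARD_FLOOR_FRAC = 0.25; // overlap error below this * sigma

struct PairTable {
  int ns;
  std::vector<double> eps, sig2, ushift, floor2;
};

static PairTable make_table(const NumericMatrix &eps_mat,
                            const NumericMatrix &sig_mat, double cutoff) {
  PairTable t;
  t.ns = eps_mat.nrow();
  t.eps.resize(t.ns * t.ns);
  t.sig2.resize(t.ns * t.ns);
  t.ushift.resize(t.ns * t.ns);
  t.floor2.resize(t.ns * t.ns);
  for (int a = 0; a < t.ns; ++a)
    for (int b = 0; b < t.ns; ++b) {
      const double eps = eps_mat(a, b), sig = sig_mat(a, b);
      const double s2 = sig * sig;
      const double src2 = s2 / (cutoff * cutoff);
      const double src6 = src2 * src2 * src2;
      t.eps[a * t.ns + b] = eps;
      t.sig2[a * t.ns + b] = s2;
      t.ushift[a * t.ns + b] = 4.0 * eps * (src6 * src6 - src6);
      t.floor2[a * t.ns + b] =
          eps > 0 ? HARD_FLOOR_FRAC * HARD_FLOOR_FRAC * s2 : 0.0;
    }
  return t;
}

// Forces, potential energy and virial (sum f.r over pairs) on raw
// column-major buffers x[i + k*n].
static void forces_raw(const double *x, const int *sp, int n,
                       const double *box, const double *invbox,
                       const PairTable &t, double cutoff, double *f,
                       double *epot, double *virial) {
  const double rc2 = cutoff * cutoff;
  std::fill(f, f + 3 * n, 0.0);
  double pe = 0.0, vir = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = x[i + n], zi = x[i + 2 * n];
    const int si = sp[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - x[j], dy = yi - x[j + n], dz = zi - x[j + 2 * n];
      dx -= box[0] * std::nearbyint(dx * invbox[0]);
      dy -= box[1] * std::nearbyint(dy * invbox[1]);
      dz -= box[2] * std::nearbyint(dz * invbox[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      const int idx = si * t.ns + sp[j];
      if (r2 < t.floor2[idx])
        stop("numerical overlap: atoms %d and %d at distance %g", i + 1,
             j + 1, std::sqrt(r2));
      const double sr2 = t.sig2[idx] / r2;
      const double sr6 = sr2 * sr2 * sr2;
      const double sr12 = sr6 * sr6;
      const double eps = t.eps[idx];
      pe += 4.0 * eps * (sr12 - sr6) - t.ushift[idx];
      const double fmag = 24.0 * eps * (2.0 * sr12 - sr6) / r2; // F/r
      vir += fmag * r2;
      f[i] += fmag * dx;           f[j] -= fmag * dx;
      f[i + n] += fmag * dy;       f[j + n] -= fmag * dy;
      f[i + 2 * n] += fmag * dz;   f[j + 2 * n] -= fmag * dz;
    }
  }
  *epot = pe;
  *virial = vir;
}

// [[Rcpp::export]]
List lj_forces_cpp(NumericMatrix pos, IntegerVector species,
                   NumericVector box, NumericMatrix eps_mat,
                   NumericMatrix sig_mat, double cutoff) {
  const int n = pos.nrow();
  PairTable t = make_table(eps_mat, sig_mat, cutoff);
  const double invbox[3] = {1 / box[0], 1 / box[1], 1 / box[2]};
  NumericMatrix f(n, 3);
  double epot, virial;
  forces_raw(REAL(pos), INTEGER(species), n, REAL(box), invbox, t, cutoff,
             REAL(f), &epot, &virial);
  return List::create(_["forces"] = f, _["epot"] = epot,
                      _["virial"] = virial);
}

// Integrate n_steps of velocity Verlet with optional Berendsen velocity
// rescaling (coupling = 0 gives NVE). Samples every sample_every steps
// (0 = no sampling). Returns final state plus stacked samples.
// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos0, NumericMatrix vel0, IntegerVector species,
                NumericVector box, NumericMatrix eps_mat, NumericMatrix sig_mat,
                double cutoff, NumericVector mass, double dt, double coupling,
                double t_target, int n_steps, int sample_every) {
  const int n = pos0.nrow();
  PairTable tab = make_table(eps_mat, sig_mat, cutoff);
  const double invbox[3] = {1 / box[0], 1 / box[1], 1 / box[2]};
  const int *sp = INTEGER(species);
  std::vector<double> x(REAL(pos0), REAL(pos0) + 3 * n);
  std::vector<double> v(REAL(vel0), REAL(vel0) + 3 * n);
  std::vector<double> f(3 * n), m(REAL(mass), REAL(mass) + n);
  double epot, virial;
  forces_raw(x.data(), sp, n, REAL(box), invbox, tab, cutoff, f.data(),
             &epot, &virial);

  const int n_samples = sample_every > 0 ? n_steps / sample_every : 0;
  NumericVector samp_pos(n_samples > 0 ? (R_xlen_t)n_samples * n * 3 : 0);
  NumericVector samp_vel(n_samples > 0 ? (R_xlen_t)n_samples * n * 3 : 0);
  IntegerVector samp_step(n_samples);
  NumericVector samp_epot(n_samples), samp_temp(n_samples),
      samp_virp(n_samples);
  int isamp = 0;

  double acc_t = 0.0;  // time-averaged kinetic temperature accumulator
  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < n; ++i) {
        const int idx = i + k * n;
        v[idx] += 0.5 * dt * f[idx] / m[i];
        x[idx] += dt * v[idx];
        x[idx] -= box[k] * std::floor(x[idx] * invbox[k]); // wrap to [0, L)
      }
    forces_raw(x.data(), sp, n, REAL(box), invbox, tab, cutoff, f.data(),
               &epot, &virial);
    double ke = 0.0;
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < n; ++i) {
        const int idx = i + k * n;
        v[idx] += 0.5 * dt * f[idx] / m[i];
        ke += 0.5 * m[i] * v[idx] * v[idx];
      }
    double t_inst = 2.0 * ke / (3.0 * n);
    if (!std::isfinite(epot) || !std::isfinite(ke))
      stop("instability: non-finite energy at step %d", step);
    if (coupling > 0.0 && t_inst > 0.0) {
      const double lam = std::sqrt(1.0 + coupling * (t_target / t_inst - 1.0));
      for (int idx = 0; idx < 3 * n; ++idx) v[idx] *= lam;
      t_inst *= lam * lam;
    }
    acc_t += t_inst;

    if (sample_every > 0 && step % sample_every == 0) {
      const double vol = box[0] * box[1] * box[2];
      const R_xlen_t off = (R_xlen_t)isamp * n * 3;
      std::copy(x.begin(), x.end(), samp_pos.begin() + off);
      std::copy(v.begin(), v.end(), samp_vel.begin() + off);
      samp_step[isamp] = step;
      samp_epot[isamp] = epot;
      samp_temp[isamp] = t_inst;
      samp_virp[isamp] = (double)n / vol * t_inst + virial / (3.0 * vol);
      ++isamp;
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  std::copy(x.begin(), x.end(), REAL(pos_out));
  std::copy(v.begin(), v.end(), REAL(vel_out));
  return List::create(
      _["pos"] = pos_out, _["vel"] = vel_out, _["epot"] = epot,
      _["mean_temp"] = n_steps > 0 ? acc_t / n_steps : NA_REAL,
      _["samples_pos"] = samp_pos, _["samples_vel"] = samp_vel,
      _["samples_step"] = samp_step, _["samples_epot"] = samp_epot,
      _["samples_temp"] = samp_temp, _["samples_pressure"] = samp_virp,
      _["n_samples"] = n_samples);
}

// Histogram of minimum-image pair distances between species a and b for one
// snapshot. Counts ordered pairs (each unordered same-species pair twice;
// self-pairs excluded). Half-open bins [k dr, (k+1) dr); r == r_max is
// discarded.
// [[Rcpp::export]]
IntegerVector pair_histogram_cpp(NumericMatrix pos, IntegerVector species,
                                 NumericVector box, int spec_a, int spec_b,
                                 double r_max, int n_bins) {
  const int n = pos.nrow();
  const double *x = REAL(pos);
  const int *sp = INTEGER(species);
  const double invbox[3] = {1 / box[0], 1 / box[1], 1 / box[2]};
  IntegerVector counts(n_bins);
  const double inv_dr = n_bins / r_max;
  const double r2max = r_max * r_max;
  for (int i = 0; i < n; ++i) {
    if (sp[i] != spec_a) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i || sp[j] != spec_b) continue;
      double dx = x[i] - x[j], dy = x[i + n] - x[j + n],
             dz = x[i + 2 * n] - x[j + 2 * n];
      dx -= box[0] * std::nearbyint(dx * invbox[0]);
      dy -= box[1] * std::nearbyint(dy * invbox[1]);
      dz -= box[2] * std::nearbyint(dz * invbox[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= r2max) continue;
      const int bin = (int)(std::sqrt(r2) * inv_dr);
      if (bin >= 0 && bin < n_bins) ++counts[bin];
    }
  }
  return counts;
}

// Smallest minimum-image pair distance (used by configuration initialization
// and overlap checks).
// [[Rcpp::export]]
double min_pair_distance_cpp(NumericMatrix pos, NumericVector box) {
  const int n = pos.nrow();
  const double *x = REAL(pos);
  const double invbox[3] = {1 / box[0], 1 / box[1], 1 / box[2]};
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = x[i + n] - x[j + n],
             dz = x[i + 2 * n] - x[j + 2 * n];
      dx -= box[0] * std::nearbyint(dx * invbox[0]);
      dy -= box[1] * std::nearbyint(dy * invbox[1]);
      dz -= box[2] * std::nearbyint(dz * invbox[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}
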