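// Compiled core: Go-model energy/forces, overdamped Brownian propagation,
// Kabsch RMSD, 1-D diffusive wells with first-passage oracles, and native
// contact counting.  All randomness draws from R's RNG so that set.seed()
// in R fully determines every trajectory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct GoModel {
  int n;
  arma::imat bonds;      // i, j (0-based)
  arma::vec bond_r0;
  double kb;
  arma::imat angles;     // i, j, k
  arma::vec angle_t0;
  double ka;
  arma::imat dihedrals;  // i, j, k, l
  arma::vec dihedral_p0;
  double kd1, kd3;
  arma::imat contacts;   // i, j
  arma::vec contact_r0;
  arma::vec contact_eps;
  arma::imat evpairs;    // i, j
  double ev_sigma, ev_eps;
  arma::imat wca;        // i, j of delete-attractive (mutated) pairs
  arma::vec wca_r0, wca_eps;
};

arma::imat idx_mat(const NumericMatrix& m, int ncol) {
  arma::imat out(m.nrow(), ncol);
  for (int r = 0; r < m.nrow(); ++r)
    for (int c = 0; c < ncol; ++c)
      out(r, c) = (int) m(r, c) - 1;  // to 0-based
  return out;
}

GoModel parse_model(const List& ml) {
  GoModel g;
  g.n = as<int>(ml["n"]);
  NumericMatrix b = ml["bonds"];
  g.bonds = b.nrow() ? idx_mat(b, 2) : arma::imat(0, 2);
  g.bond_r0.set_size(b.nrow());
  for (int r = 0; r < b.nrow(); ++r) g.bond_r0(r) = b(r, 2);
  g.kb = as<double>(ml["kb"]);
  NumericMatrix a = ml["angles"];
  g.angles = a.nrow() ? idx_mat(a, 3) : arma::imat(0, 3);
  g.angle_t0.set_size(a.nrow());
  for (int r = 0; r < a.nrow(); ++r) g.angle_t0(r) = a(r, 3);
  g.ka = as<double>(ml["ka"]);
  NumericMatrix d = ml["dihedrals"];
  g.dihedrals = d.nrow() ? idx_mat(d, 4) : arma::imat(0, 4);
  g.dihedral_p0.set_size(d.nrow());
  for (int r = 0; r < d.nrow(); ++r) g.dihedral_p0(r) = d(r, 4);
  g.kd1 = as<double>(ml["kd1"]);
  g.kd3 = as<double>(ml["kd3"]);
  NumericMatrix c = ml["contacts"];
  g.contacts = c.nrow() ? idx_mat(c, 2) : arma::imat(0, 2);
  g.contact_r0.set_size(c.nrow());
  g.contact_eps.set_size(c.nrow());
  for (int r = 0; r < c.nrow(); ++r) {
    g.contact_r0(r) = c(r, 2);
    g.contact_eps(r) = c(r, 3);
  }
  NumericMatrix e = ml["evpairs"];
  g.evpairs = e.nrow() ? idx_mat(e, 2) : arma::imat(0, 2);
  g.ev_sigma = as<double>(ml["evSigma"]);
  g.ev_eps = as<double>(ml["evEps"]);
  NumericMatrix w = ml["wca"];
  g.wca = w.nrow() ? idx_mat(w, 2) : arma::imat(0, 2);
  g.wca_r0.set_size(w.nrow());
  g.wca_eps.set_size(w.nrow());
  for (int r = 0; r < w.nrow(); ++r) {
    g.wca_r0(r) = w(r, 2);
    g.wca_eps(r) = w(r, 3);
  }
  return g;
}

const double HARD_FLOOR = 0.05;  // Angstrom; below this pair distance the
                                 // r^-12 terms overflow and energy is invalid

// Energy and (optionally) forces, allocation-free inner loops (this kernel
// runs once per integration step).  X is n x 3 column-major; F likewise,
// zeroed by the caller.
inline void vsub(const double* X, int i, int j, int n, double* out) {
  out[0] = X[i] - X[j];
  out[1] = X[i + n] - X[j + n];
  out[2] = X[i + 2 * n] - X[j + 2 * n];
}
inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline void faxpy(double* F, int i, int n, double c, const double* v) {
  F[i] += c * v[0];
  F[i + n] += c * v[1];
  F[i + 2 * n] += c * v[2];
}

double go_energy(const GoModel& g, const arma::mat& Xm, arma::mat* Fm) {
  const int n = g.n;
  const double* X = Xm.memptr();
  double* F = Fm ? Fm->memptr() : nullptr;
  double E = 0.0;
  double a[3], b[3], c[3], m[3], nn[3], tmp[3];
  // bonds: 0.5 kb (r - r0)^2
  for (arma::uword t = 0; t < g.bonds.n_rows; ++t) {
    int i = g.bonds(t, 0), j = g.bonds(t, 1);
    vsub(X, i, j, n, a);
    double r = std::sqrt(vdot(a, a));
    double dr = r - g.bond_r0(t);
    E += 0.5 * g.kb * dr * dr;
    if (F && r > 1e-12) {
      double cfac = -g.kb * dr / r;
      faxpy(F, i, n, cfac, a);
      faxpy(F, j, n, -cfac, a);
    }
  }
  // angles: 0.5 ka (theta - theta0)^2
  for (arma::uword t = 0; t < g.angles.n_rows; ++t) {
    int i = g.angles(t, 0), j = g.angles(t, 1), k = g.angles(t, 2);
    vsub(X, i, j, n, a);             // rij
    vsub(X, k, j, n, b);             // rkj
    double nij = std::sqrt(vdot(a, a)), nkj = std::sqrt(vdot(b, b));
    double ct = vdot(a, b) / (nij * nkj);
    ct = std::max(-1.0, std::min(1.0, ct));
    double theta = std::acos(ct);
    double dt = theta - g.angle_t0(t);
    E += 0.5 * g.ka * dt * dt;
    if (F) {
      // sin(theta) floored at 0.1: keeps the near-collinear singularity
      // of dtheta/dr bounded (standard practice for C-alpha angle terms)
      double st = std::sqrt(std::max(1e-2, 1.0 - ct * ct));
      double pref = -g.ka * dt;
      for (int d = 0; d < 3; ++d) {
        double uij = a[d] / nij, ukj = b[d] / nkj;
        double dti = (ct * uij - ukj) / (nij * st);
        double dtk = (ct * ukj - uij) / (nkj * st);
        F[i + d * n] += pref * dti;
        F[k + d * n] += pref * dtk;
        F[j + d * n] -= pref * (dti + dtk);
      }
    }
  }
  // dihedrals: kd1 (1 - cos(dphi)) + kd3 (1 - cos(3 dphi))
  for (arma::uword t = 0; t < g.dihedrals.n_rows; ++t) {
    int i = g.dihedrals(t, 0), j = g.dihedrals(t, 1);
    int k = g.dihedrals(t, 2), l = g.dihedrals(t, 3);
    vsub(X, j, i, n, a);             // b1
    vsub(X, k, j, n, b);             // b2
    vsub(X, l, k, n, c);             // b3
    vcross(a, b, m);
    vcross(b, c, nn);
    double mm = vdot(m, m), nnn = vdot(nn, nn);
    double bb = vdot(b, b);
    // the torsion is ill-conditioned when three beads approach
    // collinearity (|m| or |n| -> 0, dphi/dr -> inf); the whole term is
    // switched off below sin = 0.1 of the flanking bond angles so energy
    // and force stay consistent
    if (mm < 1e-2 * vdot(a, a) * bb || nnn < 1e-2 * bb * vdot(c, c) ||
        bb < 1e-12) continue;
    double nb2 = std::sqrt(bb);
    vcross(m, nn, tmp);
    double phi = std::atan2(vdot(tmp, b) / nb2, vdot(m, nn));
    double dphi = phi - g.dihedral_p0(t);
    E += g.kd1 * (1.0 - std::cos(dphi)) +
         g.kd3 * (1.0 - std::cos(3.0 * dphi));
    if (F) {
      double dE = g.kd1 * std::sin(dphi) +
                  3.0 * g.kd3 * std::sin(3.0 * dphi);
      double ci = -nb2 / mm, cl = nb2 / nnn;
      double s12 = vdot(a, b) / bb, s32 = vdot(c, b) / bb;
      for (int d = 0; d < 3; ++d) {
        double di = ci * m[d];
        double dl = cl * nn[d];
        double dj = (-1.0 - s12) * di + s32 * dl;
        double dk = s12 * di - (1.0 + s32) * dl;
        F[i + d * n] -= dE * di;
        F[j + d * n] -= dE * dj;
        F[k + d * n] -= dE * dk;
        F[l + d * n] -= dE * dl;
      }
    }
  }
  // native contacts: eps (5 (r0/r)^12 - 6 (r0/r)^10), minimum -eps at r0
  for (arma::uword t = 0; t < g.contacts.n_rows; ++t) {
    int i = g.contacts(t, 0), j = g.contacts(t, 1);
    double eps = g.contact_eps(t);
    vsub(X, i, j, n, a);
    double r2 = vdot(a, a);
    double r = std::sqrt(r2);
    if (r < HARD_FLOOR) return arma::datum::inf;
    double s2 = g.contact_r0(t) * g.contact_r0(t) / r2;
    double s10 = s2 * s2 * s2 * s2 * s2, s12 = s10 * s2;
    E += eps * (5.0 * s12 - 6.0 * s10);
    if (F) {
      // dE/dr = 60 eps (s10 - s12)/r; force = -dE/dr * rhat
      double cfac = -60.0 * eps * (s10 - s12) / r2;
      faxpy(F, i, n, cfac, a);
      faxpy(F, j, n, -cfac, a);
    }
  }
  // delete-attractive (mutated) native pairs: only the repulsive core of
  // the 12-10 well survives (WCA split: V + eps below r0, zero beyond),
  // so removing a mutation's attraction can never lower the energy
  for (arma::uword t = 0; t < g.wca.n_rows; ++t) {
    int i = g.wca(t, 0), j = g.wca(t, 1);
    double eps = g.wca_eps(t);
    vsub(X, i, j, n, a);
    double r2 = vdot(a, a);
    if (r2 < HARD_FLOOR * HARD_FLOOR) return arma::datum::inf;
    double r02 = g.wca_r0(t) * g.wca_r0(t);
    if (r2 >= r02) continue;
    double s2 = r02 / r2;
    double s10 = s2 * s2 * s2 * s2 * s2, s12 = s10 * s2;
    E += eps * (5.0 * s12 - 6.0 * s10) + eps;
    if (F) {
      double cfac = -60.0 * eps * (s10 - s12) / r2;
      faxpy(F, i, n, cfac, a);
      faxpy(F, j, n, -cfac, a);
    }
  }
  // excluded volume: ev_eps (sigma/r)^12 on non-native, non-local pairs
  const double sig2 = g.ev_sigma * g.ev_sigma;
  const double rcut2 = sig2 / (0.4 * 0.4);  // negligible beyond 2.5 sigma
  for (arma::uword t = 0; t < g.evpairs.n_rows; ++t) {
    int i = g.evpairs(t, 0), j = g.evpairs(t, 1);
    vsub(X, i, j, n, a);
    double r2 = vdot(a, a);
    if (r2 < HARD_FLOOR * HARD_FLOOR) return arma::datum::inf;
    if (r2 > rcut2) continue;
    double s2 = sig2 / r2;
    double s12 = s2 * s2 * s2 * s2 * s2 * s2;
    E += g.ev_eps * s12;
    if (F) {
      double cfac = 12.0 * g.ev_eps * s12 / r2;
      faxpy(F, i, n, cfac, a);
      faxpy(F, j, n, -cfac, a);
    }
  }
  return E;
}

// Gaussian draws via the polar (Marsaglia) method on R's uniform stream:
// noticeably cheaper than inversion for the millions of draws per segment,
// still fully determined by set.seed() in R.
struct PolarGauss {
  double spare = 0.0;
  bool have = false;
  double operator()() {
    if (have) {
      have = false;
      return spare;
    }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    have = true;
    return u * f;
  }
};

}  // namespace

// [[Rcpp::export]]
double cpp_energy(const List& model, const arma::mat& X) {
  GoModel g = parse_model(model);
  return go_energy(g, X, nullptr);
}

// [[Rcpp::export]]
List cpp_energy_forces(const List& model, const arma::mat& X) {
  GoModel g = parse_model(model);
  arma::mat F(X.n_rows, 3, arma::fill::zeros);
  double E = go_energy(g, X, &F);
  return List::create(_["energy"] = E, _["forces"] = F);
}

// Overdamped Brownian propagation:
//   x <- x + (D dt / kT) F + xi,   xi ~ N(0, 2 D dt) per coordinate.
// Samples stored every sample_every steps (0 = end only).
// [[Rcpp::export]]
List cpp_propagate(const List& model, const arma::mat& X0, int nsteps,
                   double dt, double D, double kT, int sample_every,
                   double max_disp) {
  GoModel g = parse_model(model);
  arma::mat X = X0;
  arma::mat F(X.n_rows, 3, arma::fill::zeros);
  const double mob = D * dt / kT;
  const double sd = std::sqrt(2.0 * D * dt);
  int nsamp = sample_every > 0 ? nsteps / sample_every : 0;
  List samples(nsamp);
  int si = 0;
  RNGScope scope;
  PolarGauss gauss;
  for (int step = 1; step <= nsteps; ++step) {
    F.zeros();
    double E = go_energy(g, X, &F);
    if (!std::isfinite(E))
      stop("non-finite energy: beads overlap below the hard floor");
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      for (int c = 0; c < 3; ++c) {
        double dx = mob * F(i, c) + sd * gauss();
        if (std::fabs(dx) > max_disp)
          stop("timestep too large: per-step displacement %.3f exceeds the "
               "sanity bound %.3f", std::fabs(dx), max_disp);
        X(i, c) += dx;
      }
    }
    if (sample_every > 0 && step % sample_every == 0)
      samples[si++] = X;
  }
  return List::create(_["end"] = X, _["samples"] = samples);
}

// Minimized (Kabsch) RMSD between two N x 3 coordinate sets.
// [[Rcpp::export]]
double cpp_rmsd(const arma::mat& X, const arma::mat& Y) {
  if (X.n_rows != Y.n_rows || X.n_rows < 3)
    stop("RMSD needs two conformations with the same number (>= 3) of beads");
  arma::mat Xc = X.each_row() - arma::mean(X, 0);
  arma::mat Yc = Y.each_row() - arma::mean(Y, 0);
  arma::mat H = Xc.t() * Yc;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("SVD failure in superposition");
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  double tr = s(0) + s(1) + d * s(2);
  double msd = (arma::accu(Xc % Xc) + arma::accu(Yc % Yc) - 2.0 * tr) /
               (double) X.n_rows;
  return std::sqrt(std::max(0.0, msd));
}

namespace {
// 1-D well family on u = x / a:
//   double: V = h (u^2 - 1)^2          minima at +-a, barrier h at 0
//   triple: V = h 6.75 u^2 (u^2 - 1)^2 minima at 0, +-a, barriers h between
inline double well_V(double x, double h, double a, int type) {
  double u = x / a, u2 = u * u;
  if (type == 3) return h * 6.75 * u2 * (u2 - 1.0) * (u2 - 1.0);
  double q = u2 - 1.0;
  return h * q * q;
}
inline double well_F(double x, double h, double a, int type) {
  double u = x / a, u2 = u * u;
  if (type == 3) {
    // dV/du = 6.75 h (2u (u2-1)^2 + u2 * 2 (u2-1) * 2u)
    double dVdu = 6.75 * h * 2.0 * u * (u2 - 1.0) * (3.0 * u2 - 1.0);
    return -dVdu / a;
  }
  double dVdu = 4.0 * h * u * (u2 - 1.0);
  return -dVdu / a;
}
}  // namespace

// [[Rcpp::export]]
double cpp_well_V(double x, double h, double a, int type) {
  return well_V(x, h, a, type);
}

// [[Rcpp::export]]
List cpp_dw_propagate(double x0, int nsteps, double dt, double D, double kT,
                      double h, double a, int type, int sample_every) {
  const double mob = D * dt / kT;
  const double sd = std::sqrt(2.0 * D * dt);
  int nsamp = sample_every > 0 ? nsteps / sample_every : 0;
  NumericVector samples(nsamp);
  int si = 0;
  double x = x0;
  RNGScope scope;
  PolarGauss gauss;
  for (int step = 1; step <= nsteps; ++step) {
    x += mob * well_F(x, h, a, type) + sd * gauss();
    if (sample_every > 0 && step % sample_every == 0) samples[si++] = x;
  }
  return List::create(_["end"] = x, _["samples"] = samples);
}

// Brute-force first-passage oracle: run from x0 until x crosses the target
// boundary (x >= target if target > x0, else x <= target), record the event
// time, reset to x0, repeat.  Returns event times (possibly fewer than
// n_events if the step budget is exhausted).
// [[Rcpp::export]]
NumericVector cpp_dw_fpt(double x0, double target, int n_events,
                         double dt, double D, double kT, double h, double a,
                         int type, double max_steps) {
  const double mob = D * dt / kT;
  const double sd = std::sqrt(2.0 * D * dt);
  const bool up = target > x0;
  std::vector<double> times;
  times.reserve(n_events);
  double x = x0;
  double t = 0.0;
  double total = 0.0;
  RNGScope scope;
  PolarGauss gauss;
  while ((int) times.size() < n_events && total < max_steps) {
    x += mob * well_F(x, h, a, type) + sd * gauss();
    t += dt;
    total += 1.0;
    if ((up && x >= target) || (!up && x <= target)) {
      times.push_back(t);
      x = x0;
      t = 0.0;
    }
  }
  return wrap(times);
}

// Long-run occupancy histogram for the 1-D wells; breaks must be sorted,
// outermost bins absorb over/underflow (same convention as the WE binner).
// [[Rcpp::export]]
NumericVector cpp_dw_histogram(double x0, double nsteps, double dt, double D,
                               double kT, double h, double a, int type,
                               int sample_every, NumericVector breaks) {
  int nb = breaks.size() + 1;
  NumericVector counts(nb);
  const double mob = D * dt / kT;
  const double sd = std::sqrt(2.0 * D * dt);
  double x = x0;
  RNGScope scope;
  PolarGauss gauss;
  for (double step = 1; step <= nsteps; ++step) {
    x += mob * well_F(x, h, a, type) + sd * gauss();
    if (((long long) step) % sample_every == 0) {
      int b = std::upper_bound(breaks.begin(), breaks.end(), x) - breaks.begin();
      counts[b] += 1.0;
    }
  }
  return counts;
}

// Per-frame, per-residue formed native contact counts.  A contact (i, j) is
// formed when its pair distance <= factor * r0.  frames: list of N x 3
// matrices.  Returns nframes x nres counts.
// [[Rcpp::export]]
NumericMatrix cpp_contact_counts(const List& frames, const IntegerVector& ci,
                                 const IntegerVector& cj,
                                 const NumericVector& r0, double factor,
                                 int nres) {
  int nf = frames.size(), nc = ci.size();
  NumericMatrix out(nf, nres);
  for (int f = 0; f < nf; ++f) {
    arma::mat X = as<arma::mat>(frames[f]);
    for (int t = 0; t < nc; ++t) {
      int i = ci[t] - 1, j = cj[t] - 1;
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
             dz = X(i, 2) - X(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r <= factor * r0[t]) {
        out(f, i) += 1.0;
        out(f, j) += 1.0;
      }
    }
  }
  return out;
}
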