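// Langevin dynamics core for bead-spring polyampholyte chains with explicit
// counterions, plus overdamped radial walkers and the independent-block
// renewal Monte Carlo. Everything runs at kT = 1, sigma = 1, m = 1 reduced
// units; randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct FF {
  double eps_lj, sigma, rc_mm, lB, rc_coul, eps_wca, rc_wca;
  double fene_k, fene_rmax, kT, zeta, L;
  double shift_mm, shift_wca;
};

FF make_ff(const List& p) {
  FF f;
  f.eps_lj    = as<double>(p["eps_lj"]);
  f.sigma     = as<double>(p["sigma"]);
  f.rc_mm     = as<double>(p["rc_mm"]);
  f.lB        = as<double>(p["bjerrum"]);
  f.rc_coul   = as<double>(p["rc_coul"]);
  f.eps_wca   = as<double>(p["eps_wca"]);
  f.rc_wca    = as<double>(p["rc_wca"]);
  f.fene_k    = as<double>(p["fene_k"]);
  f.fene_rmax = as<double>(p["fene_rmax"]);
  f.kT        = as<double>(p["kT"]);
  f.zeta      = as<double>(p["zeta"]);
  f.L         = as<double>(p["box_L"]);
  auto tail = [&](double eps, double rc) {
    double x6 = std::pow(f.sigma / rc, 6.0);
    return 4.0 * eps * (x6 * x6 - x6);
  };
  f.shift_mm  = tail(f.eps_lj, f.rc_mm);
  f.shift_wca = tail(f.eps_wca, f.rc_wca);
  return f;
}

// pair + bond forces; returns potential energy, fills F (length 3n).
// pair_fcap > 0 clamps each *non-bonded* pair force (overlap relaxation);
// FENE bond forces are never capped so bonds cannot be overstretched by a
// weakened restoring force.
double compute_fu(const double* X, int n, const double* q, const int* sp,
                  const int* b1, const int* b2, int nb,
                  const FF& ff, double* F, double pair_fcap = 0.0) {
  double U = 0.0;
  std::fill(F, F + 3 * n, 0.0);
  std::vector<bool> bonded;
  if (pair_fcap > 0.0) {           // bonded pairs keep full forces
    bonded.assign(static_cast<size_t>(n) * n, false);
    for (int e = 0; e < nb; ++e) {
      bonded[static_cast<size_t>(b1[e]) * n + b2[e]] = true;
      bonded[static_cast<size_t>(b2[e]) * n + b1[e]] = true;
    }
  }
  const double L = ff.L;
  const bool periodic = R_finite(L) && L > 0.0;
  const double rc_c2 = ff.rc_coul * ff.rc_coul;
  const double rc_mm2 = ff.rc_mm * ff.rc_mm;
  const double rc_wca2 = ff.rc_wca * ff.rc_wca;
  const double s2u = ff.sigma * ff.sigma;

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dd = X[3 * i + k] - X[3 * j + k];
        if (periodic) dd -= L * std::nearbyint(dd / L);
        d[k] = dd;
        r2 += dd * dd;
      }
      if (r2 < 1e-12)
        stop("overlapping particles %d and %d (r ~ 0)", i + 1, j + 1);
      const bool ion = (sp[i] == 2 || sp[j] == 2);
      const double eps   = ion ? ff.eps_wca  : ff.eps_lj;
      const double rc2   = ion ? rc_wca2     : rc_mm2;
      const double shift = ion ? ff.shift_wca : ff.shift_mm;
      double fr = 0.0; // (force magnitude)/r along d, positive = repulsive
      if (r2 < rc2) {
        double s2 = s2u / r2;
        double s6 = s2 * s2 * s2;
        U += 4.0 * eps * (s6 * s6 - s6) - shift;
        fr += 24.0 * eps * (2.0 * s6 * s6 - s6) / r2;
      }
      double qq = q[i] * q[j];
      if (qq != 0.0 && r2 < rc_c2) {
        double r = std::sqrt(r2);
        U += qq * ff.lB * (1.0 / r - 1.0 / ff.rc_coul);
        fr += qq * ff.lB / (r2 * r);
      }
      if (fr != 0.0) {
        if (pair_fcap > 0.0 &&
            !bonded[static_cast<size_t>(i) * n + j]) {
          double fmag = std::fabs(fr) * std::sqrt(r2);
          if (fmag > pair_fcap) fr *= pair_fcap / fmag;
        }
        for (int k = 0; k < 3; ++k) {
          F[3 * i + k] += fr * d[k];
          F[3 * j + k] -= fr * d[k];
        }
      }
    }
  }

  const double rm2 = ff.fene_rmax * ff.fene_rmax;
  for (int e = 0; e < nb; ++e) {
    int i = b1[e], j = b2[e];
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double dd = X[3 * i + k] - X[3 * j + k];
      if (periodic) dd -= L * std::nearbyint(dd / L);
      d[k] = dd;
      r2 += dd * dd;
    }
    if (r2 >= rm2)
      stop("FENE bond %d-%d overstretched (r = %.4f >= rmax = %.3f)",
           i + 1, j + 1, std::sqrt(r2), ff.fene_rmax);
    double fac = 1.0 - r2 / rm2;
    U += -0.5 * ff.fene_k * rm2 * std::log(fac);
    double fr = -ff.fene_k / fac; // attractive
    for (int k = 0; k < 3; ++k) {
      F[3 * i + k] += fr * d[k];
      F[3 * j + k] -= fr * d[k];
    }
  }
  return U;
}

} // namespace

// [[Rcpp::export]]
List cpp_forces_energy(NumericMatrix pos, NumericVector charge,
                       IntegerVector species, IntegerMatrix bonds,
                       List params) {
  FF ff = make_ff(params);
  int n = pos.nrow(), nb = bonds.nrow();
  std::vector<double> X(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = pos(i, k);
  std::vector<int> b1(nb), b2(nb);
  for (int e = 0; e < nb; ++e) { b1[e] = bonds(e, 0) - 1; b2[e] = bonds(e, 1) - 1; }
  double U = compute_fu(X.data(), n, REAL(charge), INTEGER(species),
                        b1.data(), b2.data(), nb, ff, F.data());
  NumericMatrix Fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Fm(i, k) = F[3 * i + k];
  return List::create(_["forces"] = Fm, _["energy"] = U);
}

// BAOAB Langevin integrator (reduces to velocity Verlet at zeta = 0).
// Records positions every `stride` steps (frame 0 = initial state).
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos0, NumericMatrix vel0, NumericVector charge,
                IntegerVector species, IntegerMatrix bonds, List params,
                int n_steps, int stride, double dt, double fcap, bool noise) {
  FF ff = make_ff(params);
  int n = pos0.nrow(), nb = bonds.nrow();
  std::vector<double> X(3 * n), V(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      X[3 * i + k] = pos0(i, k);
      V[3 * i + k] = vel0(i, k);
    }
  std::vector<int> b1(nb), b2(nb);
  for (int e = 0; e < nb; ++e) { b1[e] = bonds(e, 0) - 1; b2[e] = bonds(e, 1) - 1; }

  const int nfr = n_steps / stride + 1;
  NumericVector traj(static_cast<R_xlen_t>(nfr) * 3 * n);
  NumericVector Ut(nfr), Kt(nfr);

  double c1 = std::exp(-ff.zeta * dt);
  double c2 = noise ? std::sqrt(ff.kT * (1.0 - c1 * c1)) : 0.0;

  double U = compute_fu(X.data(), n, REAL(charge), INTEGER(species),
                        b1.data(), b2.data(), nb, ff, F.data(), fcap);

  auto kinetic = [&]() {
    double K = 0;
    for (int i = 0; i < 3 * n; ++i) K += V[i] * V[i];
    return 0.5 * K;
  };
  auto record = [&](int f) {
    R_xlen_t off = static_cast<R_xlen_t>(f) * 3 * n;
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < n; ++i) traj[off + k * n + i] = X[3 * i + k];
    Ut[f] = U;
    Kt[f] = kinetic();
  };
  record(0);

  const double hdt = 0.5 * dt;
  int frame = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) V[i] += hdt * F[i];
    for (int i = 0; i < 3 * n; ++i) X[i] += hdt * V[i];
    if (c2 > 0.0) {
      for (int i = 0; i < 3 * n; ++i) V[i] = c1 * V[i] + c2 * R::norm_rand();
    } else if (c1 != 1.0) {
      for (int i = 0; i < 3 * n; ++i) V[i] *= c1;
    }
    for (int i = 0; i < 3 * n; ++i) X[i] += hdt * V[i];
    U = compute_fu(X.data(), n, REAL(charge), INTEGER(species),
                   b1.data(), b2.data(), nb, ff, F.data(), fcap);
    for (int i = 0; i < 3 * n; ++i) V[i] += hdt * F[i];
    if (step % stride == 0) {
      if (!R_finite(U) || !R_finite(X[0]))
        stop("simulation failure: non-finite state at step %d", step);
      record(frame++);
    }
    if (step % 10000 == 0) Rcpp::checkUserInterrupt();
  }

  traj.attr("dim") = IntegerVector::create(n, 3, nfr);
  NumericMatrix Vm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Vm(i, k) = V[3 * i + k];
  return List::create(_["pos"] = traj, _["vel"] = Vm,
                      _["potential"] = Ut, _["kinetic"] = Kt);
}

namespace {
inline double polyval(const NumericVector& c, double r) {
  double v = 0;
  for (int i = c.size() - 1; i >= 0; --i) v = v * r + c[i];
  return v;
}
inline double polyder(const NumericVector& c, double r) {
  double v = 0;
  for (int i = c.size() - 1; i >= 1; --i) v = v * r + i * c[i];
  return v;
}
} // namespace

// Overdamped radial walkers in V(r) (polynomial, coef[0] + coef[1] r + ...)
// with entropic drift 2D/r so the stationary law is r^2 exp(-V).
// First-passage times to r_abs starting from r0; reflecting walls at lo, hi.
// Times at t_max are censored (caller checks).
// [[Rcpp::export]]
NumericVector cpp_fp_walk_times(NumericVector coef, double D, double r0,
                                double r_abs, double lo, double hi,
                                double dt, int n_walkers, double t_max) {
  const bool up = r_abs > r0;
  const double sq = std::sqrt(2.0 * D * dt);
  NumericVector out(n_walkers);
  for (int w = 0; w < n_walkers; ++w) {
    double r = r0, t = 0.0;
    for (;;) {
      double drift = -D * polyder(coef, r) + 2.0 * D / r;
      r += drift * dt + sq * R::norm_rand();
      t += dt;
      if (r < lo) r = 2.0 * lo - r;
      if (r > hi) r = 2.0 * hi - r;
      if (up ? (r >= r_abs) : (r <= r_abs)) break;
      if (t >= t_max) break;
    }
    out[w] = t;
    if (w % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Single overdamped radial walk, recorded every `stride` steps.
// [[Rcpp::export]]
NumericVector cpp_radial_walk(NumericVector coef, double D, double r0,
                              double lo, double hi, double dt,
                              double n_steps, int stride) {
  const double sq = std::sqrt(2.0 * D * dt);
  R_xlen_t ns = static_cast<R_xlen_t>(n_steps);
  R_xlen_t nrec = ns / stride + 1;
  NumericVector out(nrec);
  double r = r0;
  out[0] = r;
  R_xlen_t idx = 1;
  for (R_xlen_t s = 1; s <= ns; ++s) {
    double drift = -D * polyder(coef, r) + 2.0 * D / r;
    r += drift * dt + sq * R::norm_rand();
    if (r < lo) r = 2.0 * lo - r;
    if (r > hi) r = 2.0 * hi - r;
    if (s % stride == 0) out[idx++] = r;
    if (s % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

namespace {
// dwell spec: type 0 = exponential with mean v[0]; type 1 = empirical resample
inline double draw_dwell(int type, const NumericVector& v) {
  if (type == 0) return R::exp_rand() * v[0];
  int i = static_cast<int>(unif_rand() * v.size());
  if (i >= v.size()) i = v.size() - 1;
  return v[i];
}
} // namespace

// First time all n blocks are simultaneously open (and, with ts > 0, stay
// open together for a full window ts; the reported time is the start of the
// qualifying gap). closed/open specs are per-block lists of numeric vectors.
// [[Rcpp::export]]
List cpp_toy_fp(List closed_v, List open_v, IntegerVector closed_type,
                IntegerVector open_type, NumericVector phi, double ts,
                int reps, bool all_bound, double t_max) {
  const int n = closed_v.size();
  std::vector<NumericVector> cv(n), ov(n);
  for (int i = 0; i < n; ++i) {
    cv[i] = as<NumericVector>(closed_v[i]);
    ov[i] = as<NumericVector>(open_v[i]);
  }
  NumericVector times(reps);
  LogicalVector censored(reps);
  std::vector<int> state(n);       // 1 = closed (bound)
  std::vector<double> nxt(n);

  for (int rep = 0; rep < reps; ++rep) {
    int nbound = 0;
    for (int i = 0; i < n; ++i) {
      state[i] = all_bound ? 1 : (unif_rand() < phi[i] ? 1 : 0);
      nbound += state[i];
      nxt[i] = state[i] ? draw_dwell(closed_type[i], cv[i])
                        : draw_dwell(open_type[i], ov[i]);
    }
    double t = 0.0, fp = NA_REAL;
    if (nbound == 0) {
      double gap_end = *std::min_element(nxt.begin(), nxt.end());
      if (gap_end - t >= ts) fp = 0.0;
    }
    while (ISNA(fp)) {
      int imin = 0;
      for (int i = 1; i < n; ++i) if (nxt[i] < nxt[imin]) imin = i;
      t = nxt[imin];
      if (t > t_max) break;
      if (state[imin]) { state[imin] = 0; --nbound; }
      else             { state[imin] = 1; ++nbound; }
      nxt[imin] = t + (state[imin] ? draw_dwell(closed_type[imin], cv[imin])
                                   : draw_dwell(open_type[imin], ov[imin]));
      if (nbound == 0) {
        double gap_end = *std::min_element(nxt.begin(), nxt.end());
        if (gap_end - t >= ts) fp = t;
      }
    }
    if (ISNA(fp)) { times[rep] = t_max; censored[rep] = true; }
    else          { times[rep] = fp;    censored[rep] = false; }
    if (rep % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["censored"] = censored);
}
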