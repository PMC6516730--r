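// Compute cores: Crank-Nicolson stepper for the cumulative Fokker-Planck
// equation of the LIF membrane potential, interval log-likelihoods built
// from its first-passage quantities, and Euler-Maruyama simulation of the
// LIF neuron itself (used both for data generation and as an independent
// Monte Carlo route to the ISI density in tests).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// Crank-Nicolson integrator for
//   dF/dt = -b(x,t) dF/dx + (sigma^2/2) d2F/dx2
// on [x_minus, x_th] with F(x_minus,t) = 0 (Dirichlet) and
// dF/dx(x_th,t) = 0 (Neumann, ghost node).  b(x,t) = -a (x - mu) + off(t)
// where off(t) collects the stimulus current and the post-spike current,
// both independent of x.
//
// Numerical safeguards (the likelihood needs correct log-magnitudes of
// survival probabilities as small as e^{-400} even on coarse grids):
//  * exponentially fitted (Il'in) diffusion D p/tanh(p), p = b dx / 2D,
//    which makes the spatial operator an M-matrix at any cell Peclet
//    number and reduces to central differencing as dx -> 0;
//  * Rannacher startup: the first two reported steps are taken as pairs
//    of backward-Euler half-steps, damping the oscillation excited by
//    the Heaviside initial condition;
//  * a Crank-Nicolson step that produces a negative value anywhere is
//    redone as two backward-Euler half-steps (positivity-preserving),
//    and once the threshold value falls below 1e-6 the stepper locks
//    into that L-stable mode.
class CNSolver {
public:
  CNSolver(double a, double mu, double sigma, double dt, double dx,
           double x_minus, double x_th)
    : a_(a), mu_(mu), dt_(dt), dx_(dx), x_minus_(x_minus) {
    nx_ = (int) std::lround((x_th - x_minus) / dx) + 1;
    if (nx_ < 4) stop("PDE grid needs at least 4 nodes in x");
    D_ = 0.5 * sigma * sigma;
    x_.resize(nx_);
    for (int i = 0; i < nx_; ++i) x_[i] = x_minus + i * dx;
    F_.assign(nx_, 0.0);
    int m = nx_ - 1;
    sub_.assign(m, 0.0); dia_.assign(m, 0.0); sup_.assign(m, 0.0);
    rhs_.assign(m, 0.0); cp_.assign(m, 0.0); dp_.assign(m, 0.0);
    lo_.assign(nx_, 0.0); ce_.assign(nx_, 0.0); up_.assign(nx_, 0.0);
    Fbak_.assign(nx_, 0.0);
    be_lock_ = false;
  }

  int nx() const { return nx_; }
  const std::vector<double>& F() const { return F_; }

  void init(double x_start) {
    for (int i = 0; i < nx_; ++i)
      F_[i] = (x_[i] >= x_start - 1e-12) ? 1.0 : 0.0;
    // cell-average value at the step node halves the O(dx) bias of the
    // Heaviside initial condition
    for (int i = 1; i < nx_ - 1; ++i)
      if (std::fabs(x_[i] - x_start) < 1e-12) F_[i] = 0.5;
    F_[0] = 0.0;  // absorbing-in-CDF lower boundary
    be_lock_ = false;
  }

  // spatial operator coefficients for the current drift offset, with
  // exponentially fitted diffusion (M-matrix at any Peclet number)
  void build(double offset) {
    for (int i = 1; i < nx_ - 1; ++i) {
      const double b = -a_ * (x_[i] - mu_) + offset;
      const double p = b * dx_ / (2.0 * D_);
      const double Deff = (std::fabs(p) < 1e-8) ? D_ : D_ * p / std::tanh(p);
      lo_[i] = Deff / (dx_ * dx_) + b / (2.0 * dx_);
      ce_[i] = -2.0 * Deff / (dx_ * dx_);
      up_[i] = Deff / (dx_ * dx_) - b / (2.0 * dx_);
    }
    // Neumann node at x_th via ghost point (advection term vanishes)
    lo_[nx_ - 1] = 2.0 * D_ / (dx_ * dx_);
    ce_[nx_ - 1] = -2.0 * D_ / (dx_ * dx_);
    up_[nx_ - 1] = 0.0;
  }

  // one theta-step of size h using the built coefficients; theta = 0.5
  // is Crank-Nicolson, theta = 1 backward Euler
  double step(double h, double theta) {
    const int m = nx_ - 1;          // unknown nodes 1..nx-1
    const double ri = h * theta, re = h * (1.0 - theta);
    for (int j = 0; j < m; ++j) {
      const int i = j + 1;
      const double fm1 = F_[i - 1];  // F at node 0 is 0, consistent
      const double fp1 = (i < nx_ - 1) ? F_[i + 1] : 0.0;
      rhs_[j] = F_[i] + re * (lo_[i] * fm1 + ce_[i] * F_[i] + up_[i] * fp1);
      dia_[j] = 1.0 - ri * ce_[i];
      sub_[j] = (j == 0) ? 0.0 : -ri * lo_[i];  // node 0 is Dirichlet: drop
      sup_[j] = -ri * up_[i];
    }
    // Thomas algorithm
    cp_[0] = sup_[0] / dia_[0];
    dp_[0] = rhs_[0] / dia_[0];
    for (int j = 1; j < m; ++j) {
      const double den = dia_[j] - sub_[j] * cp_[j - 1];
      cp_[j] = sup_[j] / den;
      dp_[j] = (rhs_[j] - sub_[j] * dp_[j - 1]) / den;
    }
    F_[nx_ - 1] = dp_[m - 1];
    for (int j = m - 2; j >= 0; --j)
      F_[j + 1] = dp_[j] - cp_[j] * F_[j + 2];
    F_[0] = 0.0;
    return F_[nx_ - 1];
  }

  // one reported step of size dt (see class comment for the stepping
  // policy); returns F(x_th) after the step
  double report_step(double offset, int step_index, int rannacher = 2) {
    build(offset);
    double fth;
    if (step_index < rannacher || be_lock_) {
      step(0.5 * dt_, 1.0);
      fth = step(0.5 * dt_, 1.0);
    } else {
      Fbak_ = F_;
      fth = step(dt_, 0.5);
      bool neg = false;
      for (int i = 0; i < nx_; ++i) if (F_[i] < 0.0) { neg = true; break; }
      if (neg) {
        F_ = Fbak_;
        step(0.5 * dt_, 1.0);
        fth = step(0.5 * dt_, 1.0);
      }
    }
    if (fth < 1e-6) be_lock_ = true;
    return fth;
  }

private:
  double a_, mu_, D_, dt_, dx_, x_minus_;
  int nx_;
  bool be_lock_;
  std::vector<double> x_, F_, Fbak_, sub_, dia_, sup_, rhs_, cp_, dp_,
    lo_, ce_, up_;
};

// linear interpolation of the survival curve F(x_th, .) sampled at
// j*dt, clamped into [0, 1] (round-off can push F marginally past 1)
double surv_at(const std::vector<double>& Fth, double t, double dt) {
  const int n = (int) Fth.size() - 1;
  double v;
  if (t <= 0.0) v = Fth[0];
  else {
    double u = t / dt;
    if (u >= n) v = Fth[n];
    else {
      int j = (int) std::floor(u);
      double w = u - j;
      v = (1.0 - w) * Fth[j] + w * Fth[j + 1];
    }
  }
  return std::min(std::max(v, 0.0), 1.0);
}

// ISI density g(t) = -dF(x_th,t)/dt by central differences in t
// (one-sided at the ends), linearly interpolated, clipped at 0
double dens_at(const std::vector<double>& Fth, double t, double dt) {
  const int n = (int) Fth.size() - 1;
  if (n < 2) return 0.0;
  double u = t / dt;
  if (u <= 0.0) u = 0.0;
  if (u >= n) u = (double) n;
  int j0 = (int) std::floor(u);
  if (j0 >= n) j0 = n - 1;
  const double w = u - j0;
  auto gnode = [&](int j) -> double {
    double g;
    if (j <= 0) g = -(Fth[1] - Fth[0]) / dt;
    else if (j >= n) g = -(Fth[n] - Fth[n - 1]) / dt;
    else g = -(Fth[j + 1] - Fth[j - 1]) / (2.0 * dt);
    return (g > 0.0) ? g : 0.0;
  };
  return (1.0 - w) * gnode(j0) + w * gnode(j0 + 1);
}

// exponential accumulators of the spike-response kernel
// H(t) = eta1 * A0 * exp(-eta2 (t - t0)) - eta3 * B0 * exp(-eta4 (t - t0))
// for a set of spikes all <= t0
struct KernelState {
  double A0, B0;
  KernelState(const std::vector<double>& spikes, double t0,
              double eta2, double eta4) : A0(0.0), B0(0.0) {
    for (double tj : spikes) {
      const double d = t0 - tj;
      if (d < 0) continue;        // callers guarantee spikes <= t0
      A0 += std::exp(-eta2 * d);
      B0 += std::exp(-eta4 * d);
    }
  }
};

}  // namespace

// Solve the CDF-form Fokker-Planck equation for a supplied sequence of
// half-step drift offsets.  Returns the threshold trace F(x_th, j*dt)
// and optionally the full surface (nodes x in rows, time in columns).
// [[Rcpp::export]]
List cpp_fpt_solve(NumericVector offsets, double a, double mu, double sigma,
                   double dt, double dx, double x_minus, double x_th,
                   double x_start, bool full_surface = false) {
  CNSolver solver(a, mu, sigma, dt, dx, x_minus, x_th);
  const int nsteps = offsets.size();
  solver.init(x_start);
  NumericVector Fth(nsteps + 1);
  Fth[0] = solver.F().back();
  NumericMatrix surf;
  if (full_surface) {
    surf = NumericMatrix(solver.nx(), nsteps + 1);
    for (int i = 0; i < solver.nx(); ++i) surf(i, 0) = solver.F()[i];
  }
  for (int j = 0; j < nsteps; ++j) {
    Fth[j + 1] = solver.report_step(offsets[j], j);
    if (full_surface)
      for (int i = 0; i < solver.nx(); ++i) surf(i, j + 1) = solver.F()[i];
  }
  List out = List::create(_["Fth"] = Fth, _["nx"] = solver.nx());
  if (full_surface) out["F"] = surf;
  return out;
}

// Interval log-likelihood of the spikes observed in [Tb, Te), conditional
// on the spike history before the interval, for a batch of particles that
// differ only in the piecewise-constant stimulus values before (s_prev)
// and inside (s_curr) the interval.  The solve for the ISI straddling Tb
// starts at the last history spike (or the window start) and is
// conditioned on survival up to Tb, which makes interval products
// telescope to the full-trajectory likelihood.
// [[Rcpp::export]]
NumericVector cpp_interval_loglik(double Tb, double Te,
                                  NumericVector seg_spikes,
                                  NumericVector hist_spikes,
                                  double window_start,
                                  NumericVector s_prev, NumericVector s_curr,
                                  double a, double mu, double sigma,
                                  double x0, double x_th, double x_minus,
                                  NumericVector eta,
                                  double dt, double dx, double t_cap) {
  const int P = s_curr.size();
  if (s_prev.size() != P) stop("s_prev and s_curr must have equal length");
  const double e1 = eta[0], e2 = eta[1], e3 = eta[2], e4 = eta[3];
  const int L = seg_spikes.size();

  std::vector<double> hist(hist_spikes.begin(), hist_spikes.end());
  std::sort(hist.begin(), hist.end());

  NumericVector out(P);

  // ---- helpers ------------------------------------------------------
  // number of PDE steps needed to cover relative horizon T (plus a pad
  // of two steps so central differencing of g is available at T)
  auto nsteps_for = [&](double T) -> int {
    double Tc = std::min(std::max(T, 0.0), t_cap);
    int n = (int) std::ceil(Tc / dt) + 2;
    return std::max(n, 3);
  };

  // Solve one segment for one particle.  Origin t0 (absolute), spikes in
  // `hs` are all <= t0, membrane restarts at x0.  Offset at absolute
  // half-step time tau: s_prev if tau < Tb else s_curr, plus H(tau).
  // Results delivered through the threshold trace.
  auto run_segment = [&](double t0, const KernelState& ks,
                         double sprev, double scurr, int nst,
                         std::vector<double>& Fth) {
    CNSolver solver(a, mu, sigma, dt, dx, x_minus, x_th);
    solver.init(x0);
    Fth.assign(nst + 1, 0.0);
    Fth[0] = solver.F().back();
    for (int j = 0; j < nst; ++j) {
      const double taurel = (j + 0.5) * dt;
      const double tau = t0 + taurel;
      const double H = e1 * ks.A0 * std::exp(-e2 * taurel)
                     - e3 * ks.B0 * std::exp(-e4 * taurel);
      const double s = (tau < Tb) ? sprev : scurr;
      Fth[j + 1] = solver.report_step(s + H, j);
    }
  };

  auto clampT = [&](double T) { return std::min(std::max(T, 0.0), t_cap); };
  auto safelog = [](double v) {
    return (v > 0.0) ? std::log(v) : R_NegInf;
  };
  // log(num / den) with underflow treated as an impossible particle
  // (-Inf), never NaN: a vanished conditioning survival means the
  // particle assigns probability 0 to the observed history
  auto logratio = [](double num, double den) {
    if (!(num > 0.0) || !(den > 0.0)) return R_NegInf;
    return std::log(num) - std::log(den);
  };

  // ---- segment bookkeeping shared across particles -------------------
  const double t0_left = hist.empty() ? window_start : hist.back();
  KernelState ks_left(hist, t0_left, e2, e4);

  std::vector<double> Fth;      // reused buffer

  for (int p = 0; p < P; ++p) {
    const double sp = s_prev[p], sc = s_curr[p];
    double ll = 0.0;

    if (L == 0) {
      const double Tend = clampT(Te - t0_left);
      const double Tbeg = clampT(Tb - t0_left);
      run_segment(t0_left, ks_left, sp, sc, nsteps_for(Tend), Fth);
      ll = logratio(surv_at(Fth, Tend, dt), surv_at(Fth, Tbeg, dt));
      out[p] = ll;
      continue;
    }

    // left boundary: density of the first in-interval spike given
    // survival up to Tb
    {
      const double t1 = seg_spikes[0];
      const double Ttar = clampT(t1 - t0_left);
      const double Tbeg = clampT(Tb - t0_left);
      run_segment(t0_left, ks_left, sp, sc,
                  nsteps_for(std::max(Ttar, Tbeg)), Fth);
      ll += logratio(dens_at(Fth, Ttar, dt), surv_at(Fth, Tbeg, dt));
    }

    // complete ISIs inside the interval, and right-boundary survival
    std::vector<double> hs(hist);
    for (int l = 0; l < L; ++l) {
      hs.push_back(seg_spikes[l]);
      const double t0 = seg_spikes[l];
      KernelState ks(hs, t0, e2, e4);
      if (l + 1 < L) {
        const double Ttar = clampT(seg_spikes[l + 1] - t0);
        run_segment(t0, ks, sp, sc, nsteps_for(Ttar), Fth);
        ll += safelog(dens_at(Fth, Ttar, dt));
      } else {
        const double Ttar = clampT(Te - t0);
        run_segment(t0, ks, sp, sc, nsteps_for(Ttar), Fth);
        ll += safelog(surv_at(Fth, Ttar, dt));
      }
      if (!std::isfinite(ll)) break;
    }
    out[p] = ll;
  }
  return out;
}

// Euler-Maruyama simulation of the LIF membrane with spike-response
// kernel and a piecewise-constant input current sampled on a fine grid.
// Uses R's RNG so runs are reproducible through set.seed().  A threshold
// crossing detected at the end of a step records a spike at the step's
// right endpoint and resets the membrane to x0.
// [[Rcpp::export]]
NumericVector cpp_sim_lif(NumericVector drive, double drive_dt,
                          double a, double mu, double sigma,
                          double x0, double x_th,
                          NumericVector eta, double sim_dt, double total_t) {
  const double e1 = eta[0], e2 = eta[1], e3 = eta[2], e4 = eta[3];
  const double dA = std::exp(-e2 * sim_dt), dB = std::exp(-e4 * sim_dt);
  const double sq = sigma * std::sqrt(sim_dt);
  const int nsteps = (int) std::lround(total_t / sim_dt);
  const int ndrive = drive.size();
  double X = x0, A = 0.0, B = 0.0;
  std::vector<double> spikes;
  spikes.reserve(1024);
  for (int i = 0; i < nsteps; ++i) {
    const double t = i * sim_dt;
    int di = (int) (t / drive_dt);
    if (di >= ndrive) di = ndrive - 1;
    const double H = e1 * A - e3 * B;
    const double b = -a * (X - mu) + drive[di] + H;
    X += b * sim_dt + sq * norm_rand();
    A *= dA; B *= dB;
    if (X >= x_th) {
      const double ts = (i + 1) * sim_dt;
      spikes.push_back(ts);
      X = x0;
      A += 1.0; B += 1.0;   // new spike starts contributing from ts on
    }
  }
  return wrap(spikes);
}

// First-passage times of the LIF membrane from x0 to x_th under a
// constant drift offset, no response kernel: the independent Monte Carlo
// oracle for the PDE route.  With `bridge`, a within-step
// Brownian-bridge crossing test removes the O(sqrt(dt)) bias of
// end-of-step detection.  Paths not absorbed by t_max are censored at
// t_max.
// [[Rcpp::export]]
NumericVector cpp_fpt_sample(int n, double offset, double a, double mu,
                             double sigma, double x0, double x_th,
                             double sim_dt, double t_max,
                             bool bridge = false) {
  NumericVector out(n);
  const double sq = sigma * std::sqrt(sim_dt);
  const double s2dt = sigma * sigma * sim_dt;
  const int nsteps = (int) std::lround(t_max / sim_dt);
  for (int k = 0; k < n; ++k) {
    double X = x0;
    double fpt = t_max;
    for (int i = 0; i < nsteps; ++i) {
      const double b = -a * (X - mu) + offset;
      const double Xn = X + b * sim_dt + sq * norm_rand();
      if (Xn >= x_th) { fpt = (i + 1) * sim_dt; break; }
      if (bridge) {
        const double pc = std::exp(-2.0 * (x_th - X) * (x_th - Xn) / s2dt);
        if (unif_rand() < pc) { fpt = (i + 0.5) * sim_dt; break; }
      }
      X = Xn;
    }
    out[k] = fpt;
  }
  return out;
}
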