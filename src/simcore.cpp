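// Numerical core: FitzHugh-Nagumo integration driven by a piecewise-
// exponential stimulus, the closed-loop two-population colony simulator,
// and a stationary shot-noise sampler.
//
// The FN unit is
//   eps1*eps2 * dv/dt = v - v^3/3 - c*u - a + s(t)
//   eps1      * du/dt = v - c*u
// with s(t) decaying exponentially (time constant tau, seconds) between
// instantaneous jumps. The fast timescale eps1*eps2 (0.01 s at defaults)
// is resolved with a fixed-step RK4; jump times are forced as mesh points
// so s is evaluated exactly at every stage.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct FNParamsC {
  double c, a, e1, e2, thr;
};

struct FNUnit {
  double v, u;
  bool above; // hysteresis flag: v currently above the spike threshold
};

inline void deriv(const FNParamsC &p, double v, double u, double s,
                  double &dv, double &du) {
  dv = (v - v * v * v / 3.0 - p.c * u - p.a + s) / (p.e1 * p.e2);
  du = (v - p.c * u) / p.e1;
}

// One RK4 step of length h; s0, sh, s1 are the stimulus at t, t+h/2, t+h.
// Returns the spike time (absolute) if an upward threshold crossing was
// detected, otherwise a negative value.
inline double rk4_step(const FNParamsC &p, FNUnit &st, double t, double h,
                       double s0, double sh, double s1) {
  double k1v, k1u, k2v, k2u, k3v, k3u, k4v, k4u;
  deriv(p, st.v, st.u, s0, k1v, k1u);
  deriv(p, st.v + 0.5 * h * k1v, st.u + 0.5 * h * k1u, sh, k2v, k2u);
  deriv(p, st.v + 0.5 * h * k2v, st.u + 0.5 * h * k2u, sh, k3v, k3u);
  deriv(p, st.v + h * k3v, st.u + h * k3u, s1, k4v, k4u);
  double v_new = st.v + h / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
  double u_new = st.u + h / 6.0 * (k1u + 2 * k2u + 2 * k3u + k4u);
  if (!R_finite(v_new) || !R_finite(u_new) || std::fabs(v_new) > 1e6)
    stop("FN integration diverged (|v| > 1e6); reduce the step size");
  double spike = -1.0;
  if (!st.above && v_new > p.thr) {
    // sub-step spike time by linear interpolation of the crossing
    double frac = (p.thr - st.v) / (v_new - st.v);
    spike = t + frac * h;
    st.above = true;
  } else if (st.above && v_new < p.thr) {
    st.above = false;
  }
  st.v = v_new;
  st.u = u_new;
  return spike;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".fn_simulate_cpp")]]
List fn_simulate_cpp(double v0, double u0, double c, double a, double e1,
                     double e2, double thr, NumericVector jump_times,
                     NumericVector jump_amounts, double s0, double tau,
                     double t0, double duration, double dt,
                     double record_dt) {
  FNParamsC p{c, a, e1, e2, thr};
  FNUnit st{v0, u0, v0 > thr};

  const double t_end = t0 + duration;
  double t = t0;
  double s_base = s0;   // stimulus value at t_base
  double t_base = t0;   // time at which s_base holds
  const bool decay = (tau > 0);

  std::vector<double> spikes;
  std::vector<double> rec_t, rec_v, rec_u, rec_s;
  const bool record = (record_dt > 0);
  double next_rec = t0;

  R_xlen_t j = 0;
  const R_xlen_t nj = jump_times.size();
  while (j < nj && jump_times[j] < t0) ++j; // ignore jumps before start

  auto s_at = [&](double tt) {
    return decay ? s_base * std::exp(-(tt - t_base) / tau) : s_base;
  };

  while (t < t_end - 1e-12) {
    double t_ev = (j < nj && jump_times[j] < t_end) ? jump_times[j] : t_end;
    // integrate up to the next jump (or the end) in fixed steps
    while (t < t_ev - 1e-12) {
      double h = std::min(dt, t_ev - t);
      if (record && t >= next_rec - 1e-12) {
        rec_t.push_back(t);
        rec_v.push_back(st.v);
        rec_u.push_back(st.u);
        rec_s.push_back(s_at(t));
        next_rec += record_dt;
      }
      double sp = rk4_step(p, st, t, h, s_at(t), s_at(t + 0.5 * h),
                           s_at(t + h));
      if (sp >= 0) spikes.push_back(sp);
      t += h;
    }
    // apply the jump exactly at its time
    if (j < nj && std::fabs(t_ev - jump_times[j]) < 1e-9) {
      s_base = s_at(jump_times[j]) + jump_amounts[j];
      t_base = jump_times[j];
      t = jump_times[j];
      ++j;
    } else {
      t = t_ev;
    }
  }
  if (record) {
    rec_t.push_back(t_end);
    rec_v.push_back(st.v);
    rec_u.push_back(st.u);
    rec_s.push_back(s_at(t_end));
  }

  return List::create(_["spike_times"] = wrap(spikes),
                      _["v"] = st.v, _["u"] = st.u,
                      _["s_end"] = s_at(t_end),
                      _["trace_t"] = wrap(rec_t), _["trace_v"] = wrap(rec_v),
                      _["trace_u"] = wrap(rec_u), _["trace_s"] = wrap(rec_s));
}

// Closed-loop colony simulation with the informed/uninformed mechanism.
// Two FN units (volatilities c_u, c_i) are driven by the common stimulus.
// A spike of the uninformed unit is kept with probability 1 - x_i and, if
// the uninformed pool is nonempty, dispatches one uninformed forager; a
// spike of the informed unit is kept with probability x_i and draws from
// the informed pool. Dispatched foragers return after 60 * chisq(D) seconds
// and join the informed pool; each return (and each exogenous arrival)
// bumps s by k. Exogenous arrivals do not touch the pools.
//' @noRd
// [[Rcpp::export(name = ".closed_loop_cpp")]]
List closed_loop_cpp(double c_u, double c_i, double a, double e1, double e2,
                     double thr, double k, double tau, double D_minutes,
                     int N, double duration, double dt,
                     NumericVector exog_times, double trace_dt) {
  FNParamsC pu{c_u, a, e1, e2, thr};
  FNParamsC pi{c_i, a, e1, e2, thr};
  // both units start at the rest equilibrium for s = 0
  double v_rest = -std::cbrt(3.0 * a);
  FNUnit uu{v_rest, v_rest / c_u, false};
  FNUnit ui{v_rest, v_rest / c_i, false};

  double t = 0.0, s_base = 0.0, t_base = 0.0;
  int n_u = N, n_i = 0;
  double x_i = 0.0;
  long dropped_u = 0, dropped_i = 0;

  std::priority_queue<double, std::vector<double>,
                      std::greater<double>> returns;

  std::vector<double> lam_u, lam_i;        // all unit spike times
  std::vector<double> out_t;               // kept departures
  std::vector<int> out_class;              // 0 = uninformed, 1 = informed
  std::vector<double> in_ret;              // simulated returns
  std::vector<double> tr_t, tr_s, tr_xi, tr_q;
  std::vector<int> tr_nu, tr_ni;
  double next_rec = 0.0;

  auto s_at = [&](double tt) {
    return s_base * std::exp(-(tt - t_base) / tau);
  };
  auto recompute_xi = [&]() {
    if (n_u + n_i > 0) x_i = double(n_i) / double(n_u + n_i);
  };
  auto handle_spike = [&](int cls, double t_sp) {
    // cls 0: uninformed unit, keep with prob 1 - x_i; cls 1: informed
    double keep_p = (cls == 0) ? (1.0 - x_i) : x_i;
    if (cls == 0) lam_u.push_back(t_sp); else lam_i.push_back(t_sp);
    if (R::unif_rand() < keep_p) {
      int &pool = (cls == 0) ? n_u : n_i;
      if (pool > 0) {
        pool -= 1;
        recompute_xi();
        out_t.push_back(t_sp);
        out_class.push_back(cls);
        double trip_s = 60.0 * R::rchisq(D_minutes);
        if (trip_s < dt) trip_s = dt;
        returns.push(t_sp + trip_s);
      } else {
        if (cls == 0) ++dropped_u; else ++dropped_i;
      }
    }
  };

  R_xlen_t j = 0;
  const R_xlen_t nj = exog_times.size();

  // The event horizon is re-read every step: departures scheduled during a
  // step enqueue new returns, which must be able to become the next event.
  while (t < duration - 1e-12) {
    double t_ev = duration;
    int ev_kind = -1; // 0 exogenous arrival, 1 return
    if (j < nj && exog_times[j] < t_ev) { t_ev = exog_times[j]; ev_kind = 0; }
    if (!returns.empty() && returns.top() < t_ev) {
      t_ev = returns.top();
      ev_kind = 1;
    }
    if (ev_kind >= 0 && t_ev <= t + 1e-12) {
      // apply the event exactly at its time
      t = t_ev;
      s_base = s_at(t_ev) + k;
      t_base = t_ev;
      if (ev_kind == 0) {
        ++j; // exogenous arrival: stimulus only
      } else {
        returns.pop();
        n_i += 1; // returning forager is informed from now on
        recompute_xi();
        in_ret.push_back(t_ev);
      }
      continue;
    }
    double h = std::min(dt, t_ev - t);
    if (trace_dt > 0 && t >= next_rec - 1e-12) {
      tr_t.push_back(t);
      tr_s.push_back(s_at(t));
      tr_xi.push_back(x_i);
      tr_nu.push_back(n_u);
      tr_ni.push_back(n_i);
      tr_q.push_back(N - n_u - n_i);
      next_rec += trace_dt;
    }
    double s0 = s_at(t), sh = s_at(t + 0.5 * h), s1 = s_at(t + h);
    // uninformed unit processed first (deterministic tie-break)
    double sp_u = rk4_step(pu, uu, t, h, s0, sh, s1);
    double sp_i = rk4_step(pi, ui, t, h, s0, sh, s1);
    if (sp_u >= 0) handle_spike(0, sp_u);
    if (sp_i >= 0) handle_spike(1, sp_i);
    t += h;
  }
  if (trace_dt > 0) { // close the trace exactly at the end of the run
    tr_t.push_back(duration);
    tr_s.push_back(s_at(duration));
    tr_xi.push_back(x_i);
    tr_nu.push_back(n_u);
    tr_ni.push_back(n_i);
    tr_q.push_back(N - n_u - n_i);
  }
  // foragers still outside at the end
  std::vector<double> pending;
  while (!returns.empty()) { pending.push_back(returns.top()); returns.pop(); }

  return List::create(
      _["lambda_u"] = wrap(lam_u), _["lambda_i"] = wrap(lam_i),
      _["out_times"] = wrap(out_t), _["out_class"] = wrap(out_class),
      _["return_times"] = wrap(in_ret),
      _["pending_returns"] = wrap(pending),
      _["dropped_uninformed"] = double(dropped_u),
      _["dropped_informed"] = double(dropped_i),
      _["n_u"] = n_u, _["n_i"] = n_i,
      _["trace_t"] = wrap(tr_t), _["trace_s"] = wrap(tr_s),
      _["trace_x_i"] = wrap(tr_xi), _["trace_n_u"] = wrap(tr_nu),
      _["trace_n_i"] = wrap(tr_ni), _["trace_q"] = wrap(tr_q));
}

// Independent draws from the stationary law of the shot-noise stimulus:
// s = k * sum_j exp(-age_j / tau) with Poisson(rate * window) events of
// i.i.d. uniform ages on (0, window). window should be >> tau.
//' @noRd
// [[Rcpp::export(name = ".shot_noise_samples_cpp")]]
NumericVector shot_noise_samples_cpp(int n, double rate, double k,
                                     double tau, double window) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int m = int(R::rpois(rate * window));
    double s = 0.0;
    for (int jj = 0; jj < m; ++jj)
      s += std::exp(-R::runif(0.0, window) / tau);
    out[i] = k * s;
  }
  return out;
}
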