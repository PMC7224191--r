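// Simulation cores for the two-pool attractor network and the extended
// independent race model. Time is in ms throughout; the synaptic equation is
// integrated in seconds internally because firing rates are in Hz.
#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

struct NetPars {
  double a, b, d, gamma, tau_S, sigma_noise, tau_noise, I0;
  double J_ext, J_self, J_cross, z, I_CD_max, tau_CD, dt, t_max;
  bool exact_ou;
};

NetPars as_net_pars(const List& p) {
  NetPars q;
  q.a = p["a"]; q.b = p["b"]; q.d = p["d"]; q.gamma = p["gamma"];
  q.tau_S = p["tau_S"]; q.sigma_noise = p["sigma_noise"];
  q.tau_noise = p["tau_noise"]; q.I0 = p["I0"];
  q.J_ext = p["J_ext"]; q.J_self = p["J_self"]; q.J_cross = p["J_cross"];
  q.z = p["z"]; q.I_CD_max = p["I_CD_max"]; q.tau_CD = p["tau_CD"];
  q.dt = p["dt"]; q.t_max = p["t_max"];
  q.exact_ou = p.containsElementNamed("exact_ou") ? as<bool>(p["exact_ou"]) : false;
  return q;
}

// effective input-output relation; removable singularity at a*I = b
inline double frate(double I, const NetPars& p) {
  double x = p.a * I - p.b;
  double dx = p.d * x;
  if (std::fabs(dx) < 1e-8) return 1.0 / p.d + 0.5 * x;
  return x / (1.0 - std::exp(-dx));
}

struct NetState {
  double S_C, S_AC, In_C, In_AC;
};

class Sim {
public:
  Sim(const NetPars& p, uint64_t seed) : p_(p), rng_(seed), nd_(0.0, 1.0) {
    dt_s_ = p.dt / 1000.0;
    if (p.exact_ou) {
      ou_decay_ = std::exp(-p.dt / p.tau_noise);
      ou_sd_ = p.sigma_noise * std::sqrt((1.0 - ou_decay_ * ou_decay_) / 2.0);
    } else {
      ou_decay_ = 1.0 - p.dt / p.tau_noise;
      ou_sd_ = p.sigma_noise * std::sqrt(p.dt / p.tau_noise);
    }
  }

  double norm() { return nd_(rng_); }
  double unif() { return std::uniform_real_distribution<double>(0.0, 1.0)(rng_); }

  // one Euler(-Maruyama) step; I_stim_* and I_CD are currents at this instant
  void step(NetState& s, double I_stim_C, double I_stim_AC, double I_CD,
            double& r_C, double& r_AC, bool noiseless = false) {
    double I_C = p_.J_self * s.S_C - p_.J_cross * s.S_AC + I_stim_C + s.In_C + I_CD;
    double I_AC = p_.J_self * s.S_AC - p_.J_cross * s.S_C + I_stim_AC + s.In_AC + I_CD;
    r_C = frate(I_C, p_);
    r_AC = frate(I_AC, p_);
    s.S_C += dt_s_ * (-s.S_C / (p_.tau_S / 1000.0) + (1.0 - s.S_C) * p_.gamma * r_C);
    s.S_AC += dt_s_ * (-s.S_AC / (p_.tau_S / 1000.0) + (1.0 - s.S_AC) * p_.gamma * r_AC);
    if (s.S_C < 0.0) s.S_C = 0.0; else if (s.S_C > 1.0) s.S_C = 1.0;
    if (s.S_AC < 0.0) s.S_AC = 0.0; else if (s.S_AC > 1.0) s.S_AC = 1.0;
    if (!noiseless) {
      s.In_C = p_.I0 + (s.In_C - p_.I0) * ou_decay_ + ou_sd_ * norm();
      s.In_AC = p_.I0 + (s.In_AC - p_.I0) * ou_decay_ + ou_sd_ * norm();
    }
  }

  const NetPars& pars() const { return p_; }

private:
  NetPars p_;
  std::mt19937_64 rng_;
  std::normal_distribution<double> nd_;
  double dt_s_, ou_decay_, ou_sd_;
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_session")]]
DataFrame cpp_simulate_session(List params, NumericVector c_signed,
                               NumericVector gap_ms, double pre_ms,
                               double seed) {
  NetPars p = as_net_pars(params);
  int n = c_signed.size();
  if (gap_ms.size() != n) stop("gap_ms must have one entry per trial");
  Sim sim(p, (uint64_t)seed);

  NetState s{0.0, 0.0, p.I0, p.I0};
  double r_C = 0.0, r_AC = 0.0;

  // settle into the neutral low-activity state under background input
  int n_pre = (int)std::floor(pre_ms / p.dt);
  for (int k = 0; k < n_pre; ++k) sim.step(s, 0.0, 0.0, 0.0, r_C, r_AC);

  IntegerVector choice(n);
  NumericVector t_dec(n), delta_r(n);
  NumericVector S_C_on(n), S_AC_on(n), S_C_dec(n), S_AC_dec(n);
  NumericVector S_C_next(n), S_AC_next(n);

  for (int i = 0; i < n; ++i) {
    double c = c_signed[i];
    double I_C = p.J_ext * (1.0 + c);   // c > 0 favors pool C
    double I_AC = p.J_ext * (1.0 - c);
    S_C_on[i] = s.S_C; S_AC_on[i] = s.S_AC;

    int n_max = (int)std::floor(p.t_max / p.dt);
    int ch = 0; double td = p.t_max, dr = 0.0;
    for (int k = 0; k < n_max; ++k) {
      sim.step(s, I_C, I_AC, 0.0, r_C, r_AC);
      if (r_C >= p.z || r_AC >= p.z) {
        if (r_C > r_AC) ch = 1;
        else if (r_AC > r_C) ch = -1;
        else ch = (sim.unif() < 0.5) ? 1 : -1;
        td = (k + 1) * p.dt;
        dr = std::fabs(r_C - r_AC);
        break;
      }
    }
    if (ch == 0) dr = std::fabs(r_C - r_AC); // timeout: balance at deadline
    choice[i] = ch; t_dec[i] = td; delta_r[i] = dr;
    S_C_dec[i] = s.S_C; S_AC_dec[i] = s.S_AC;

    // corollary-discharge relaxation from the decision (or deadline) to the
    // next stimulus onset
    int n_gap = (int)std::floor(gap_ms[i] / p.dt);
    for (int k = 0; k < n_gap; ++k) {
      double t_rel = (k + 1) * p.dt;
      double I_CD = -p.I_CD_max * std::exp(-t_rel / p.tau_CD);
      sim.step(s, 0.0, 0.0, I_CD, r_C, r_AC);
    }
    S_C_next[i] = s.S_C; S_AC_next[i] = s.S_AC;
  }

  return DataFrame::create(
    _["choice"] = choice, _["decision_time"] = t_dec, _["delta_r"] = delta_r,
    _["S_C_onset"] = S_C_on, _["S_AC_onset"] = S_AC_on,
    _["S_C_decision"] = S_C_dec, _["S_AC_decision"] = S_AC_dec,
    _["S_C_next"] = S_C_next, _["S_AC_next"] = S_AC_next);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_noiseless_flow")]]
NumericMatrix cpp_noiseless_flow(List params, double S_C0, double S_AC0,
                                 double I_stim_C, double I_stim_AC,
                                 double duration_ms) {
  NetPars p = as_net_pars(params);
  Sim sim(p, 1u);
  NetState s{S_C0, S_AC0, p.I0, p.I0};
  int n = (int)std::floor(duration_ms / p.dt);
  NumericMatrix out(n + 1, 5);
  double r_C = frate(p.J_self * s.S_C - p.J_cross * s.S_AC + I_stim_C + p.I0, p);
  double r_AC = frate(p.J_self * s.S_AC - p.J_cross * s.S_C + I_stim_AC + p.I0, p);
  out(0, 0) = 0.0; out(0, 1) = s.S_C; out(0, 2) = s.S_AC;
  out(0, 3) = r_C; out(0, 4) = r_AC;
  for (int k = 0; k < n; ++k) {
    sim.step(s, I_stim_C, I_stim_AC, 0.0, r_C, r_AC, true);
    out(k + 1, 0) = (k + 1) * p.dt;
    out(k + 1, 1) = s.S_C; out(k + 1, 2) = s.S_AC;
    out(k + 1, 3) = r_C; out(k + 1, 4) = r_AC;
  }
  colnames(out) = CharacterVector::create("time_ms", "S_C", "S_AC", "r_C", "r_AC");
  return out;
}

// ---------------------------------------------------------------------------
// extended independent race model

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_irm_session")]]
DataFrame cpp_simulate_irm_session(List params, NumericVector c_signed,
                                   NumericVector gap_ms, double seed,
                                   double collapse_rate) {
  double I0 = params["I0_drift"], sigma = params["sigma"], z = params["z_thr"];
  double relax_tau = params["relax_tau"], dt = params["dt"], t_max = params["t_max"];
  int n = c_signed.size();
  if (gap_ms.size() != n) stop("gap_ms must have one entry per trial");
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  std::uniform_real_distribution<double> ud(0.0, 1.0);
  double sq = sigma * std::sqrt(dt);

  double x_C = 0.0, x_AC = 0.0;
  IntegerVector choice(n);
  NumericVector t_dec(n), balance(n), x_C_next(n), x_AC_next(n);
  NumericVector x_C_on(n), x_AC_on(n);

  for (int i = 0; i < n; ++i) {
    double c = c_signed[i];
    double mu_C = I0 * (1.0 + c) * dt, mu_AC = I0 * (1.0 - c) * dt;
    x_C_on[i] = x_C; x_AC_on[i] = x_AC;
    int n_max = (int)std::floor(t_max / dt);
    int ch = 0; double td = t_max, bal = 0.0;
    for (int k = 0; k < n_max; ++k) {
      x_C += mu_C + sq * nd(rng);
      x_AC += mu_AC + sq * nd(rng);
      double t = (k + 1) * dt;
      double zt = z - collapse_rate * t;
      if (zt < 0.1 * z) zt = 0.1 * z;
      if (x_C >= zt || x_AC >= zt) {
        if (x_C > x_AC) { ch = 1; bal = std::fabs(zt - x_AC); }
        else if (x_AC > x_C) { ch = -1; bal = std::fabs(zt - x_C); }
        else { ch = (ud(rng) < 0.5) ? 1 : -1; bal = 0.0; }
        td = t;
        break;
      }
    }
    if (ch == 0) bal = std::fabs(z - std::min(x_C, x_AC));
    choice[i] = ch; t_dec[i] = td; balance[i] = bal;

    int n_gap = (int)std::floor(gap_ms[i] / dt);
    for (int k = 0; k < n_gap; ++k) {
      x_C += -x_C / relax_tau * dt + sq * nd(rng);
      x_AC += -x_AC / relax_tau * dt + sq * nd(rng);
    }
    x_C_next[i] = x_C; x_AC_next[i] = x_AC;
  }

  return DataFrame::create(
    _["choice"] = choice, _["decision_time"] = t_dec, _["balance"] = balance,
    _["x_C_onset"] = x_C_on, _["x_AC_onset"] = x_AC_on,
    _["x_C_next"] = x_C_next, _["x_AC_next"] = x_AC_next);
}
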