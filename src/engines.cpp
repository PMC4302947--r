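// Inner simulation loops for the BCPNN synapse engines.
//
// Three engines share one sampling contract: at every pre- or postsynaptic
// spike step the eight canonical traces plus the weight and bias readouts
// are recorded after the spike has been processed.
//
//  - euler:       explicit fixed-step Euler on the canonical ODE cascade
//  - analytical1: exact event-driven update of the canonical traces
//  - analytical2: exact event-driven update of the exponential state
//                 variables, optionally LUT-backed and/or with fixed-point
//                 storage quantisation (round to nearest, ties to even,
//                 saturating)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Coef {
  double dt, eps;
  double tau_zi, tau_zj, tau_e, tau_p_star, tau_zij;
  double ai, aj, c, aibi, ajbj, aij, bij;
  double lzi, lei, lpi, lzj, lej, lpj, lzij, leij, lpij;
};

Coef unpack(const NumericVector& v) {
  Coef c;
  c.dt = v["dt"]; c.eps = v["eps"];
  c.tau_zi = v["tau_zi"]; c.tau_zj = v["tau_zj"]; c.tau_e = v["tau_e"];
  c.tau_p_star = v["tau_p_star"]; c.tau_zij = v["tau_zij"];
  c.ai = v["ai"]; c.aj = v["aj"]; c.c = v["c"];
  c.aibi = v["aibi"]; c.ajbj = v["ajbj"];
  c.aij = v["aij"]; c.bij = v["bij"];
  c.lzi = v["lam_zi"]; c.lei = v["lam_ei"]; c.lpi = v["lam_pi"];
  c.lzj = v["lam_zj"]; c.lej = v["lam_ej"]; c.lpj = v["lam_pj"];
  c.lzij = v["lam_zij"]; c.leij = v["lam_eij"]; c.lpij = v["lam_pij"];
  return c;
}

inline double weight_of(double Pi, double Pj, double Pij, double eps) {
  return std::log((Pij + eps * eps) / ((Pi + eps) * (Pj + eps)));
}

// merged event list: step index plus pre/post flags
struct Events {
  std::vector<int> step;
  std::vector<bool> pre, post;
};

Events merge_events(const IntegerVector& pre, const IntegerVector& post) {
  Events ev;
  size_t i = 0, j = 0;
  while (i < (size_t)pre.size() || j < (size_t)post.size()) {
    int sp = i < (size_t)pre.size() ? pre[i] : INT_MAX;
    int sq = j < (size_t)post.size() ? post[j] : INT_MAX;
    int s = std::min(sp, sq);
    ev.step.push_back(s);
    ev.pre.push_back(sp == s);
    ev.post.push_back(sq == s);
    if (sp == s) ++i;
    if (sq == s) ++j;
  }
  return ev;
}

// saturating round-to-nearest-even quantiser (storage emulation)
struct Quant {
  bool on;
  double scale, lo, hi;
  Quant(int frac_bits, int int_bits) {
    on = frac_bits >= 0;
    if (on) {
      scale = std::ldexp(1.0, frac_bits);
      hi = std::ldexp(1.0, int_bits) - 1.0 / scale;
      lo = -std::ldexp(1.0, int_bits);
    } else {
      scale = 1.0; lo = 0.0; hi = 0.0;
    }
  }
  inline double q(double x) const {
    if (!on) return x;
    double v = std::nearbyint(x * scale) / scale;
    return v < lo ? lo : (v > hi ? hi : v);
  }
};

// decay factors exp(-N*dt/tau), optionally from a precomputed table;
// table entries are generated by the identical expression, so LUT and
// direct evaluation agree bit for bit inside the covered range
struct Decay {
  double dt, tau;
  std::vector<double> tab;
  void init(double dt_, double tau_, int L) {
    dt = dt_; tau = tau_;
    tab.resize(L > 0 ? L : 0);
    for (int n = 1; n <= L; ++n) tab[n - 1] = std::exp(-(n * dt) / tau);
  }
  inline double operator()(int N) const {
    if (N == 0) return 1.0;
    if (N <= (int)tab.size()) return tab[N - 1];
    return std::exp(-(N * dt) / tau);
  }
};

}  // namespace

// Explicit Euler on the canonical cascade. Spikes are unit increments to
// the Z traces applied within the step after decay; all right-hand sides
// use start-of-step values.
// [[Rcpp::export(name = ".cpp_run_euler")]]
List cpp_run_euler(IntegerVector pre_steps, IntegerVector post_steps,
                   int n_steps, NumericVector par, NumericVector init,
                   bool record_all = false) {
  const double dt = par["dt"], tau_zi = par["tau_zi"], tau_zj = par["tau_zj"],
               tau_e = par["tau_e"], tau_p = par["tau_p"],
               kappa = par["kappa"], eps = par["eps"];
  double Zi = init[0], Zj = init[1], Ei = init[2], Ej = init[3],
         Eij = init[4], Pi = init[5], Pj = init[6], Pij = init[7];
  const double kz_i = 1.0 - dt / tau_zi, kz_j = 1.0 - dt / tau_zj,
               ke = dt / tau_e, kp = dt * kappa / tau_p;

  Events ev = merge_events(pre_steps, post_steps);
  const int n_ev = ev.step.size();
  NumericMatrix out(record_all ? n_steps : n_ev, 13);
  size_t next_ev = 0;

  for (int n = 1; n <= n_steps; ++n) {
    bool sp = false, sq = false;
    if (next_ev < (size_t)n_ev && ev.step[next_ev] == n) {
      sp = ev.pre[next_ev]; sq = ev.post[next_ev];
    }
    const double Zi0 = Zi, Zj0 = Zj, Ei0 = Ei, Ej0 = Ej, Eij0 = Eij;
    Zi = Zi0 * kz_i + (sp ? 1.0 : 0.0);
    Zj = Zj0 * kz_j + (sq ? 1.0 : 0.0);
    Ei = Ei0 + ke * (Zi0 - Ei0);
    Ej = Ej0 + ke * (Zj0 - Ej0);
    Eij = Eij0 + ke * (Zi0 * Zj0 - Eij0);
    Pi += kp * (Ei0 - Pi);
    Pj += kp * (Ej0 - Pj);
    Pij += kp * (Eij0 - Pij);

    int row = -1;
    if (record_all) row = n - 1;
    else if (next_ev < (size_t)n_ev && ev.step[next_ev] == n) row = next_ev;
    if (row >= 0) {
      out(row, 0) = n; out(row, 1) = sp; out(row, 2) = sq;
      out(row, 3) = Zi; out(row, 4) = Zj; out(row, 5) = Ei; out(row, 6) = Ej;
      out(row, 7) = Eij; out(row, 8) = Pi; out(row, 9) = Pj; out(row, 10) = Pij;
      out(row, 11) = weight_of(Pi, Pj, Pij, eps);
      out(row, 12) = std::log(Pj + eps);
    }
    if (next_ev < (size_t)n_ev && ev.step[next_ev] == n) ++next_ev;
  }
  NumericVector fin = NumericVector::create(Zi, Zj, Ei, Ej, Eij, Pi, Pj, Pij);
  return List::create(_["samples"] = out, _["final"] = fin,
                      _["n_events"] = n_ev, _["n_updates"] = n_steps);
}

// Event-driven engines. method 1 advances the canonical traces with the
// exact closed forms; method 2 advances the exponential state variables
// (optionally quantised on write-back) and reconstructs the canonical
// traces for the readout.
// [[Rcpp::export(name = ".cpp_run_event")]]
List cpp_run_event(IntegerVector pre_steps, IntegerVector post_steps,
                   NumericVector coefvec, NumericVector init, int method,
                   int lut_L = 0, int frac_bits = -1, int int_bits = 10) {
  const Coef co = unpack(coefvec);
  Events ev = merge_events(pre_steps, post_steps);
  const int n_ev = ev.step.size();
  Quant qz(frac_bits, int_bits);

  Decay dzi, dzj, de, dp, dzij;
  dzi.init(co.dt, co.tau_zi, lut_L);
  dzj.init(co.dt, co.tau_zj, lut_L);
  de.init(co.dt, co.tau_e, lut_L);
  dp.init(co.dt, co.tau_p_star, lut_L);
  dzij.init(co.dt, co.tau_zij, lut_L);

  // state in the representation picked by `method`
  double s0 = init[0], s1 = init[1], s2 = init[2], s3 = init[3],
         s4 = init[4], s5 = init[5], s6 = init[6], s7 = init[7];
  int t_last = 0;

  NumericMatrix out(n_ev, 13);
  for (int k = 0; k < n_ev; ++k) {
    const int n = ev.step[k];
    const int N = n - t_last;
    const bool sp = ev.pre[k], sq = ev.post[k];
    double Zi, Zj, Ei, Ej, Eijv, Pi, Pj, Pij;

    if (method == 1) {
      // canonical: order matters, the synaptic decay sources from the Z
      // values at t_last, so it runs before the margins are decayed
      double& Zi_s = s0; double& Zj_s = s1; double& Ei_s = s2;
      double& Ej_s = s3; double& Eij_s = s4; double& Pi_s = s5;
      double& Pj_s = s6; double& Pij_s = s7;
      if (N > 0) {
        const double fzi = dzi(N), fzj = dzj(N), fe = de(N), fp = dp(N),
                     fzij = dzij(N);
        const double G = Zi_s * Zj_s, AG = co.aij * G;
        const double Eij_new = Eij_s * fe + AG * (fzij - fe);
        const double Pij_new = Pij_s * fp + (co.aij * co.bij) * G * (fzij - fp)
                               + (Eij_s - AG) * co.c * (fe - fp);
        const double AZi = co.ai * Zi_s, AZj = co.aj * Zj_s;
        const double Ei_new = Ei_s * fe + AZi * (fzi - fe);
        const double Pi_new = Pi_s * fp + co.aibi * Zi_s * (fzi - fp)
                              + (Ei_s - AZi) * co.c * (fe - fp);
        const double Ej_new = Ej_s * fe + AZj * (fzj - fe);
        const double Pj_new = Pj_s * fp + co.ajbj * Zj_s * (fzj - fp)
                              + (Ej_s - AZj) * co.c * (fe - fp);
        Zi_s *= fzi; Zj_s *= fzj;
        Ei_s = Ei_new; Ej_s = Ej_new; Eij_s = Eij_new;
        Pi_s = Pi_new; Pj_s = Pj_new; Pij_s = Pij_new;
      }
      if (sp) Zi_s += 1.0;
      if (sq) Zj_s += 1.0;
      Zi = Zi_s; Zj = Zj_s; Ei = Ei_s; Ej = Ej_s; Eijv = Eij_s;
      Pi = Pi_s; Pj = Pj_s; Pij = Pij_s;
    } else {
      // exponential state variables; consecutive evaluation, pre first
      double& Zs_i = s0; double& Zs_j = s1; double& Es_i = s2;
      double& Es_j = s3; double& Ps_i = s4; double& Ps_j = s5;
      double& Es_ij = s6; double& Ps_ij = s7;
      if (N > 0) {
        const double fzi = dzi(N), fzj = dzj(N), fe = de(N), fp = dp(N);
        Zs_i *= fzi; Zs_j *= fzj;
        Es_i *= fe; Es_j *= fe; Es_ij *= fe;
        Ps_i *= fp; Ps_j *= fp; Ps_ij *= fp;
      }
      if (sp) {
        Zs_i += 1.0; Es_i += 1.0; Ps_i += 1.0;
        Es_ij += Zs_j; Ps_ij += Zs_j;
      }
      if (sq) {
        Zs_j += 1.0; Es_j += 1.0; Ps_j += 1.0;
        Es_ij += Zs_i; Ps_ij += Zs_i;
      }
      if (qz.on) {
        Zs_i = qz.q(Zs_i); Zs_j = qz.q(Zs_j);
        Es_i = qz.q(Es_i); Es_j = qz.q(Es_j);
        Ps_i = qz.q(Ps_i); Ps_j = qz.q(Ps_j);
        Es_ij = qz.q(Es_ij); Ps_ij = qz.q(Ps_ij);
      }
      const double G = Zs_i * Zs_j;
      Zi = Zs_i; Zj = Zs_j;
      Ei = co.ai * (Zs_i - Es_i);
      Ej = co.aj * (Zs_j - Es_j);
      Eijv = co.aij * (G - Es_ij);
      // reconstructed probabilities are clamped at zero: quantized storage
      // can push the linear combination a rounding step below zero
      Pi = std::max(co.lzi * Zs_i + co.lei * Es_i + co.lpi * Ps_i, 0.0);
      Pj = std::max(co.lzj * Zs_j + co.lej * Es_j + co.lpj * Ps_j, 0.0);
      Pij = std::max(co.lzij * G + co.leij * Es_ij + co.lpij * Ps_ij, 0.0);
    }
    t_last = n;

    out(k, 0) = n; out(k, 1) = sp; out(k, 2) = sq;
    out(k, 3) = Zi; out(k, 4) = Zj; out(k, 5) = Ei; out(k, 6) = Ej;
    out(k, 7) = Eijv; out(k, 8) = Pi; out(k, 9) = Pj; out(k, 10) = Pij;
    out(k, 11) = weight_of(Pi, Pj, Pij, co.eps);
    out(k, 12) = std::log(Pj + co.eps);
  }

  NumericVector fin = NumericVector::create(s0, s1, s2, s3, s4, s5, s6, s7);
  return List::create(_["samples"] = out, _["final"] = fin,
                      _["t_last"] = t_last, _["n_events"] = n_ev,
                      _["n_updates"] = n_ev);
}
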