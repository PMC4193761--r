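// Fixed-step network integrator for conductance-based AdEx/LIF neurons.
//
// Scheme: exponential-Euler membrane update with the exponential
// spike-initiation term treated explicitly, event-driven conductance jumps on
// a delay ring buffer, closed-form Tsodyks-Markram recursions evaluated at
// presynaptic events only. All randomness lives on the R side; this loop is
// bitwise deterministic for identical inputs.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct StpState {
  double R;      // recovered resource after the last spike
  double u;      // running utilization after the last spike
  double t_last; // time of last presynaptic spike, < 0 if none
};

// Effective weight of the n-th presynaptic spike (Tsodyks-Markram).
// mode: 0 = static, 1 = depression (u fixed at U), 2 = facilitation.
inline double stp_release(StpState& s, double t, double w, int mode,
                          double U, double tau_rec, double tau_facil) {
  if (mode == 0) return w;
  double Rn, un;
  if (s.t_last < 0.0) {
    Rn = 1.0;
    un = U;
  } else {
    double dt_isi = t - s.t_last;
    Rn = 1.0 - (1.0 - s.R * (1.0 - s.u)) * std::exp(-dt_isi / tau_rec);
    un = (mode == 2) ? U + s.u * (1.0 - U) * std::exp(-dt_isi / tau_facil) : U;
  }
  s.R = Rn;
  s.u = un;
  s.t_last = t;
  return w * un * Rn;
}

} // namespace

// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(NumericMatrix neurons,
                     IntegerVector syn_source,
                     IntegerVector syn_target,
                     NumericVector syn_weight,
                     NumericVector syn_delay,
                     IntegerVector syn_receptor,
                     IntegerVector syn_stp_mode,
                     NumericVector syn_U,
                     NumericVector syn_tau_rec,
                     NumericVector syn_tau_facil,
                     int n_sources,
                     IntegerVector ext_id,
                     NumericVector ext_time,
                     double duration,
                     double dt,
                     IntegerVector record) {
  const int N = neurons.nrow();
  const int n_steps = (int)std::lround(duration / dt);
  const int n_syn = syn_source.size();
  const int n_src_total = N + n_sources;

  // Column layout of `neurons` (see R/simulate.R):
  // 0 C_m, 1 g_L, 2 E_L, 3 V_T, 4 Delta_T, 5 tau_w, 6 a, 7 b, 8 V_reset,
  // 9 V_spike, 10 tau_ref, 11 tau_e, 12 tau_i, 13 E_e, 14 E_i, 15 i_ext, 16 v0
  std::vector<double> V(N), wad(N), ge(N, 0.0), gi(N, 0.0);
  std::vector<double> dec_e(N), dec_i(N);
  std::vector<int> ref_left(N, 0), ref_steps(N);
  std::vector<double> thr(N);
  for (int i = 0; i < N; ++i) {
    V[i] = neurons(i, 16);
    wad[i] = 0.0;
    dec_e[i] = std::exp(-dt / neurons(i, 11));
    dec_i[i] = std::exp(-dt / neurons(i, 12));
    ref_steps[i] = (int)std::lround(neurons(i, 10) / dt);
    thr[i] = neurons(i, 4) > 0.0 ? neurons(i, 9) : neurons(i, 3);
  }

  // CSR over sources (network neurons first, then external sources).
  std::vector<int> offset(n_src_total + 1, 0), order(n_syn);
  for (int s = 0; s < n_syn; ++s) offset[syn_source[s]]++; // 1-based ids
  for (int i = 0; i < n_src_total; ++i) offset[i + 1] += offset[i];
  {
    std::vector<int> cursor(offset.begin(), offset.end() - 1);
    for (int s = 0; s < n_syn; ++s) order[cursor[syn_source[s] - 1]++] = s;
  }

  std::vector<int> delay_steps(n_syn);
  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s) {
    int d = (int)std::lround(syn_delay[s] / dt);
    if (d < 1) d = 1;
    delay_steps[s] = d;
    if (d > max_delay) max_delay = d;
  }
  const int ring_n = max_delay + 1;
  std::vector<std::vector<int>> ring_tgt(ring_n);
  std::vector<std::vector<double>> ring_w(ring_n);

  std::vector<StpState> stp(n_syn);
  for (int s = 0; s < n_syn; ++s) stp[s] = {1.0, syn_U[s], -1.0};

  const int n_rec = record.size();
  NumericMatrix vrec(n_rec > 0 ? n_steps + 1 : 0, n_rec);
  for (int r = 0; r < n_rec; ++r) vrec(0, r) = V[record[r] - 1];

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  spike_t.reserve(1024);
  spike_id.reserve(1024);

  // Route one presynaptic spike of source `src` (1-based) at time t.
  auto route = [&](int src, double t, int step) {
    for (int k = offset[src - 1]; k < offset[src]; ++k) {
      int s = order[k];
      double w_eff = stp_release(stp[s], t, syn_weight[s], syn_stp_mode[s],
                                 syn_U[s], syn_tau_rec[s], syn_tau_facil[s]);
      int slot = (step + delay_steps[s]) % ring_n;
      ring_tgt[slot].push_back((syn_target[s] - 1) * 2 + syn_receptor[s]);
      ring_w[slot].push_back(w_eff);
    }
  };

  int ext_ptr = 0;
  const int n_ext = ext_id.size();

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;

    // external spikes emitted in [t, t+dt)
    while (ext_ptr < n_ext && ext_time[ext_ptr] < t + dt) {
      route(ext_id[ext_ptr], ext_time[ext_ptr], step);
      ++ext_ptr;
    }

    // deliver events due at this step
    int slot = step % ring_n;
    {
      std::vector<int>& tg = ring_tgt[slot];
      std::vector<double>& wv = ring_w[slot];
      for (size_t k = 0; k < tg.size(); ++k) {
        int ti = tg[k] >> 1;
        if (tg[k] & 1) gi[ti] += wv[k]; else ge[ti] += wv[k];
      }
      tg.clear();
      wv.clear();
    }

    // neuron update
    for (int i = 0; i < N; ++i) {
      double C = neurons(i, 0) * 1000.0; // nF -> pF so that pA/pF = mV/ms
      double gL = neurons(i, 1), EL = neurons(i, 2);
      double VT = neurons(i, 3), DT = neurons(i, 4), tw = neurons(i, 5);
      double aa = neurons(i, 6);
      double w_inf = aa * (V[i] - EL);
      bool spiked = false;

      if (ref_left[i] > 0) {
        V[i] = neurons(i, 8); // clamped to reset during refractoriness
        --ref_left[i];
      } else {
        double G = gL + ge[i] + gi[i];
        double B = gL * EL + ge[i] * neurons(i, 13) + gi[i] * neurons(i, 14)
                   - wad[i] + neurons(i, 15);
        if (DT > 0.0) {
          double arg = (V[i] - VT) / DT;
          if (arg > 16.0) arg = 16.0; // bounded: spike detection handles the rest
          B += gL * DT * std::exp(arg);
        }
        double Vinf = B / G;
        double decay = std::exp(-G * dt / C);
        V[i] = Vinf + (V[i] - Vinf) * decay;
        if (!std::isfinite(V[i]))
          stop("numerical divergence: membrane potential of neuron %d is not finite at t = %f ms",
               i + 1, t);
        if (V[i] >= thr[i]) {
          spiked = true;
          spike_t.push_back(t + dt);
          spike_id.push_back(i + 1);
          V[i] = neurons(i, 8);
          ref_left[i] = ref_steps[i];
          route(i + 1, t + dt, step);
        }
      }

      wad[i] = w_inf + (wad[i] - w_inf) * std::exp(-dt / tw);
      if (spiked) wad[i] += neurons(i, 7);

      ge[i] *= dec_e[i];
      gi[i] *= dec_i[i];
    }

    if (n_rec > 0)
      for (int r = 0; r < n_rec; ++r) vrec(step + 1, r) = V[record[r] - 1];

    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["spike_time"] = wrap(spike_t),
                      _["spike_neuron"] = wrap(spike_id),
                      _["voltages"] = vrec);
}

// Bernoulli instantiation of a distance-dependent Gaussian connection profile
// on a torus of side L: p(d) = min(1, p0 * exp(-d^2 / (2 sigma^2))) with the
// minimum-image metric. Uses R's RNG so that set.seed() on the R side governs
// the draw. Returns 1-based (row of src, row of tgt) index pairs.
// [[Rcpp::export(name = ".torus_connect_cpp")]]
List torus_connect_cpp(NumericVector xs, NumericVector ys,
                       NumericVector xt, NumericVector yt,
                       double L, double sigma, double p0,
                       bool allow_self) {
  const int ns = xs.size(), nt = xt.size();
  std::vector<int> si, ti;
  std::vector<double> dist;
  const double half = L / 2.0, inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int i = 0; i < ns; ++i) {
    for (int j = 0; j < nt; ++j) {
      if (!allow_self && i == j) continue;
      double dx = std::fabs(xs[i] - xt[j]);
      double dy = std::fabs(ys[i] - yt[j]);
      if (dx > half) dx = L - dx;
      if (dy > half) dy = L - dy;
      double d2 = dx * dx + dy * dy;
      double p = p0 * std::exp(-d2 * inv2s2);
      if (p > 1.0) p = 1.0;
      if (R::unif_rand() < p) {
        si.push_back(i + 1);
        ti.push_back(j + 1);
        dist.push_back(std::sqrt(d2));
      }
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["source"] = wrap(si), _["target"] = wrap(ti),
                      _["distance"] = wrap(dist));
}

// Expected in-degree for the profile above at prefactor p0 = 1, evaluated for
// `probe` source positions against all targets; used to normalize p0 so that
// a configured expected in-degree is met.
// [[Rcpp::export(name = ".torus_kernel_mass_cpp")]]
NumericVector torus_kernel_mass_cpp(NumericVector xs, NumericVector ys,
                                    NumericVector xt, NumericVector yt,
                                    double L, double sigma,
                                    bool allow_self) {
  const int ns = xs.size(), nt = xt.size();
  NumericVector mass(ns);
  const double half = L / 2.0, inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int i = 0; i < ns; ++i) {
    double m = 0.0;
    for (int j = 0; j < nt; ++j) {
      if (!allow_self && i == j) continue;
      double dx = std::fabs(xs[i] - xt[j]);
      double dy = std::fabs(ys[i] - yt[j]);
      if (dx > half) dx = L - dx;
      if (dy > half) dy = L - dy;
      m += std::exp(-(dx * dx + dy * dy) * inv2s2);
    }
    mass[i] = m;
  }
  return mass;
}
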