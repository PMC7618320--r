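// Fixed-step exponential-Euler integrator for a leaky integrate-and-fire
// network with alpha-function conductance synapses, independent Poisson
// background input per neuron, piecewise-constant injected currents, and
// optional conductance probes sampled every step.
//
// Units: ms, mV, nS, pF, pA. Alpha synapses are implemented as the exact
// two-state linear system x' = -x/tau, g' = -g/tau + x; a spike with weight w
// adds w*e/tau to x so the conductance transient peaks at w (nS).

#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List lif_simulate_cpp(NumericMatrix W,         // N x N, W(j,i) = weight i->j, nS (magnitudes)
                      LogicalVector is_exc,    // presynaptic class per neuron
                      double dt, double t_max, // ms
                      NumericVector bg_rate,   // Hz per neuron (excitatory events)
                      double bg_weight,        // nS per background event
                      NumericMatrix stim_current, // N x n_intervals, pA
                      NumericVector stim_start, NumericVector stim_end, // ms
                      IntegerVector probe_idx, // 1-based neurons to record g
                      List params, int seed) {
  const int N = W.nrow();
  const double C_m = params["C_m"], g_L = params["g_L"], E_L = params["E_L"];
  const double V_th = params["V_th"], V_reset = params["V_reset"];
  const double E_ex = params["E_ex"], E_in = params["E_in"];
  const double tau_ref = params["tau_ref"], tau_E = params["tau_E"];
  const double tau_I = params["tau_I"], delay = params["delay"];

  const int n_steps = (int)std::round(t_max / dt);
  const int delay_steps = std::max(1, (int)std::round(delay / dt));
  const double decE = std::exp(-dt / tau_E), decI = std::exp(-dt / tau_I);
  const double kickE = std::exp(1.0) / tau_E, kickI = std::exp(1.0) / tau_I;
  const int ref_steps = (int)std::round(tau_ref / dt);

  std::vector<double> V(N, E_L), xE(N, 0), gE(N, 0), xI(N, 0), gI(N, 0);
  std::vector<int> refr(N, 0);
  std::vector<std::vector<int>> pending(delay_steps + 1);

  std::mt19937_64 rng(seed);
  std::poisson_distribution<int> pois;
  std::vector<double> bg_mean(N);
  for (int i = 0; i < N; ++i) bg_mean[i] = bg_rate[i] * dt / 1000.0;

  const int n_int = stim_current.ncol();
  const int n_probe = probe_idx.size();
  NumericMatrix pgE(n_probe > 0 ? n_steps : 0, n_probe);
  NumericMatrix pgI(n_probe > 0 ? n_steps : 0, n_probe);

  std::vector<int> spk_n;
  std::vector<double> spk_t;
  spk_n.reserve(100000);
  spk_t.reserve(100000);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const int slot = step % (delay_steps + 1);

    // deliver delayed spikes
    for (int i : pending[slot]) {
      if (is_exc[i]) {
        for (int j = 0; j < N; ++j) {
          double w = W(j, i);
          if (w != 0) xE[j] += w * kickE;
        }
      } else {
        for (int j = 0; j < N; ++j) {
          double w = W(j, i);
          if (w != 0) xI[j] += w * kickI;
        }
      }
    }
    pending[slot].clear();

    // external currents active now
    double I_ext_col = -1;
    // (allow overlapping intervals; sum them)
    for (int i = 0; i < N; ++i) {
      // background input
      if (bg_mean[i] > 0) {
        int k = pois(rng, std::poisson_distribution<int>::param_type(bg_mean[i]));
        if (k > 0) xE[i] += k * bg_weight * kickE;
      }
      // conductance states (exact update for the alpha system)
      gE[i] = decE * (gE[i] + dt * xE[i]);
      xE[i] *= decE;
      gI[i] = decI * (gI[i] + dt * xI[i]);
      xI[i] *= decI;

      double I_ext = 0;
      for (int c = 0; c < n_int; ++c) {
        if (t >= stim_start[c] && t < stim_end[c]) I_ext += stim_current(i, c);
      }

      if (refr[i] > 0) {
        --refr[i];
        V[i] = V_reset;
        continue;
      }
      const double g_tot = g_L + gE[i] + gI[i];
      const double V_inf = (g_L * E_L + gE[i] * E_ex + gI[i] * E_in + I_ext) / g_tot;
      V[i] = V_inf + (V[i] - V_inf) * std::exp(-g_tot * dt / C_m);
      if (V[i] >= V_th) {
        spk_n.push_back(i + 1);
        spk_t.push_back(t + dt);
        V[i] = V_reset;
        refr[i] = ref_steps;
        pending[(step + delay_steps) % (delay_steps + 1)].push_back(i);
      }
    }
    for (int pb = 0; pb < n_probe; ++pb) {
      pgE(step, pb) = gE[probe_idx[pb] - 1];
      pgI(step, pb) = gI[probe_idx[pb] - 1];
    }
    (void)I_ext_col;
  }

  return List::create(_["spike_neuron"] = wrap(spk_n),
                      _["spike_time"] = wrap(spk_t),
                      _["g_E"] = pgE, _["g_I"] = pgI,
                      _["n_steps"] = n_steps, _["dt"] = dt);
}
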