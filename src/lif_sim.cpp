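// Forward-Euler integration of the clustered E/I leaky integrate-and-fire
// network. Membrane potentials follow
//   dV/dt = -(V - V_L)/tau_m + (I_ext(t) + I_syn(t)) / C
// and synaptic currents follow
//   dI_syn/dt = -I_syn/tau_syn + (1/tau_syn) * sum_j J_ij * delta(t - t_j)
// with separate traces (and time constants) for excitatory and
// inhibitory presynaptic input. Weights are stored positive; the
// inhibitory sign is applied here when a presynaptic inhibitory neuron
// spikes. The simulation is fully deterministic given the initial
// membrane potentials: there is no ongoing noise source.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate_lif(int n_steps, double dt,
                      IntegerVector w_p, IntegerVector w_i,
                      NumericVector w_x,
                      LogicalVector is_inh,
                      NumericVector v0,
                      NumericVector tau_m, double v_l, double v_th,
                      double v_r, NumericVector tau_r,
                      NumericVector tau_syn_e, NumericVector tau_syn_i,
                      NumericVector i_ext,
                      LogicalVector stim_target, NumericVector stim_f,
                      LogicalVector gate_target, NumericVector gate_g,
                      NumericVector sil_f, bool gate_total,
                      double noise_sd, int noise_steps,
                      IntegerVector noise_seed,
                      IntegerVector noise_group) {
  const int n = v0.size();
  if (stim_f.size() < n_steps || gate_g.size() < n_steps ||
      sil_f.size() < n_steps)
    stop("stimulus/gate/silencing waveforms shorter than n_steps");
  std::vector<double> V(v0.begin(), v0.end());
  // synaptic traces in single precision: their magnitudes are O(1-10)
  // and the ongoing noise dwarfs float rounding, while the halved
  // memory traffic speeds up the hot loop considerably
  std::vector<float> synE(n, 0.0f), synI(n, 0.0f);
  std::vector<float> decE(n), decI(n);
  std::vector<double> inv_tau_m(n);
  std::vector<float> inv_tsE(n), inv_tsI(n);
  std::vector<int> refr(n, 0), refr_steps(n);
  for (int i = 0; i < n; ++i) {
    decE[i] = (float)(1.0 - dt / tau_syn_e[i]);
    decI[i] = (float)(1.0 - dt / tau_syn_i[i]);
    inv_tau_m[i] = 1.0 / tau_m[i];
    inv_tsE[i] = (float)(1.0 / tau_syn_e[i]);
    inv_tsI[i] = (float)(1.0 / tau_syn_i[i]);
    refr_steps[i] = (int)std::lround(tau_r[i] / dt);
  }
  std::vector<int> fired;
  fired.reserve(256);
  std::vector<double> sp_time;
  std::vector<int> sp_neuron;
  sp_time.reserve(1 << 17);
  sp_neuron.reserve(1 << 17);

  const int* pp = INTEGER(w_p);
  const int* pi_ = INTEGER(w_i);
  const double* px = REAL(w_x);

  // Piecewise-constant Gaussian noise current, refreshed every
  // noise_steps integration steps, from a dedicated xorshift128+
  // stream so that the simulation stays reproducible from its seed.
  uint64_t ns0 = 0x9E3779B97F4A7C15ULL, ns1 = 0xBF58476D1CE4E5B9ULL;
  for (int k = 0; k < noise_seed.size(); ++k) {
    ns0 ^= (uint64_t)(uint32_t)noise_seed[k] * 0x2545F4914F6CDD1DULL + k;
    ns1 ^= ns0 + 0x632BE59BD9B4E019ULL;
  }
  auto xrand = [&]() -> double {
    uint64_t x = ns0, y = ns1;
    ns0 = y;
    x ^= x << 23;
    ns1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return (double)((ns1 + y) >> 11) * (1.0 / 9007199254740992.0);
  };
  // noise is shared within groups (cluster x E/I): group-correlated
  // afferent fluctuations are what move cluster-level dynamics
  int n_groups = 0;
  for (int i = 0; i < n; ++i)
    if (noise_group[i] + 1 > n_groups) n_groups = noise_group[i] + 1;
  std::vector<double> gnoise(std::max(n_groups, 1), 0.0);
  bool use_noise = noise_sd > 0.0 && noise_steps > 0;

  for (int t = 0; t < n_steps; ++t) {
    const double sf = stim_f[t], gg = gate_g[t], ph = sil_f[t];
    if (use_noise && t % noise_steps == 0) {
      for (int g = 0; g < n_groups; ++g) {
        // Box-Muller
        double u1 = xrand(), u2 = xrand();
        if (u1 < 1e-300) u1 = 1e-300;
        gnoise[g] = noise_sd *
          std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
      }
    }
    // integrate, decay and detect threshold crossings in one pass
    fired.clear();
    const double tnow = (t + 1) * dt;
    const double sfac = 1.0 + sf / 100.0, pfac = 1.0 + ph / 100.0;
    for (int i = 0; i < n; ++i) {
      double sE = synE[i], sI = synI[i];
      synE[i] *= decE[i];
      synI[i] *= decI[i];
      if (refr[i] > 0) { --refr[i]; V[i] = v_r; continue; }
      double iext = i_ext[i];
      if (!is_inh[i]) {
        if (stim_target[i]) iext *= sfac;
      } else {
        iext *= pfac;
      }
      double isyn;
      if (gate_target[i]) {
        // the gate withholds (excitatory, or all) synaptic input from
        // action-cluster neurons until the lateral spouts approach
        isyn = gate_total ? gg * (sE + sI) : gg * sE + sI;
      } else {
        isyn = sE + sI;
      }
      double v = V[i] + dt * (-(V[i] - v_l) * inv_tau_m[i] + iext + isyn +
                              (use_noise ? gnoise[noise_group[i]] : 0.0));
      if (v >= v_th) {
        v = v_r;
        refr[i] = refr_steps[i];
        fired.push_back(i);
        sp_time.push_back(tnow);
        sp_neuron.push_back(i + 1);
      } else if (!(v > -1e6)) {
        stop("membrane potential diverged at step %d (neuron %d)", t + 1,
             i + 1);
      }
      V[i] = v;
    }
    // propagate: increments take effect from the next step on
    for (int f : fired) {
      const bool inh = is_inh[f];
      for (int k = pp[f]; k < pp[f + 1]; ++k) {
        int post = pi_[k];
        if (inh) synI[post] -= (float)px[k] * inv_tsI[post];
        else     synE[post] += (float)px[k] * inv_tsE[post];
      }
    }
  }
  return List::create(_["time"] = NumericVector(sp_time.begin(),
                                                sp_time.end()),
                      _["neuron"] = IntegerVector(sp_neuron.begin(),
                                                  sp_neuron.end()));
}
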