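#include <Rcpp.h>
using namespace Rcpp;

// Adaptive leaky integrate-and-fire membrane with three slow processes:
//  - a linearised h-type (sag) conductance: activation s relaxes toward
//    (EL - V)/(EL - Eh) with time constant taus and carries current
//    gs * s * (Eh - V); hyperpolarisation activates a depolarising current,
//    producing the characteristic sag relaxation,
//  - a spike-triggered adaptation current w (increment b per spike, decay tauw),
//  - a slow rectified Ornstein-Uhlenbeck modulation x of the spike
//    threshold (vth + stut_amp * max(x, 0), stut_amp in mV): excitability
//    is intermittently gated off, producing stuttering/irregular firing
//    without disturbing subthreshold responses or the rheobase.
// Background variability is an OU current chosen so the subthreshold voltage
// fluctuation has standard deviation noise_sd (mV).
//
// Integration: fixed step at the sampling interval dt (ms); the voltage
// uses an exponential-Euler update (exact for the passive subsystem, so
// the pure-RC limit reproduces the analytic charging curve to rounding),
// the slow linear states use exact exponential decay, and the OU processes
// use their exact discrete-time transition.
// Spike: V crossing vth from below; V is reset to vreset and clamped there
// for tref ms. Spike samples are marked; a stylised waveform is stamped in R.
//
// Parameter vector layout (all named on the R side):
//  0 C_pF, 1 gL_nS, 2 EL_mV, 3 vth_mV, 4 vreset_mV, 5 tref_ms,
//  6 gs_nS, 7 taus_ms, 8 Eh_mV, 9 b_pA, 10 tauw_ms,
//  11 stut_amp, 12 stut_tau_ms, 13 noise_sd_mV

// [[Rcpp::export]]
List integrate_alif_cpp(NumericVector par, double i_amp,
                        int n_pre, int n_step, int n_post, double dt) {
  const double C = par[0], gL = par[1], EL = par[2], vth = par[3],
               vreset = par[4], tref = par[5], gs = par[6], taus = par[7],
               Eh = par[8], b = par[9], tauw = par[10], stut_amp = par[11],
               stut_tau = par[12], noise_sd = par[13];

  const int n = n_pre + n_step + n_post;
  NumericVector V(n);
  std::vector<int> spikes;

  const bool use_noise = noise_sd > 0.0;
  const bool use_stut = stut_amp > 0.0;
  const bool use_sag = gs > 0.0;

  // OU current noise calibrated so stationary voltage sd ~ noise_sd
  const double tau_n = 1.0;                       // ms, noise correlation time
  const double tau_m = C / gL;                    // ms
  const double sigma_I = use_noise
      ? noise_sd * gL * std::sqrt((tau_n + tau_m) / tau_n)
      : 0.0;

  double v = EL, s = 0.0, w = 0.0;
  double u = use_noise ? sigma_I * R::norm_rand() : 0.0;   // stationary start
  double x = use_stut ? R::norm_rand() : 0.0;
  int ref_left = 0;
  const int ref_steps = (int) std::lround(tref / dt);
  const double sag_denom = Eh - EL;               // validated nonzero in R

  // exact discrete-time transition coefficients for the slow states
  const double du = std::exp(-dt / tau_n);
  const double su = use_noise ? sigma_I * std::sqrt(1.0 - du * du) : 0.0;
  const double dx = use_stut ? std::exp(-dt / stut_tau) : 1.0;
  const double sx = use_stut ? std::sqrt(1.0 - dx * dx) : 0.0;
  const double dw = (b > 0.0) ? std::exp(-dt / tauw) : 1.0;

  for (int i = 0; i < n; ++i) {
    const double I_inj = (i >= n_pre && i < n_pre + n_step) ? i_amp : 0.0;

    if (use_noise) u = u * du + su * R::norm_rand();
    if (use_stut) x = x * dx + sx * R::norm_rand();
    if (use_sag)
      s += dt / taus * ((EL - v) / sag_denom - s);
    if (b > 0.0) w *= dw;

    const double vth_eff = use_stut ? vth + stut_amp * std::max(x, 0.0) : vth;

    if (ref_left > 0) {
      v = vreset;
      --ref_left;
    } else {
      // exponential-Euler voltage update: the sag current
      // gs*s*(Eh - v) contributes a conductance gs*s and a drive
      // gs*s*Eh, held over the step
      const double g_tot = gL + (use_sag ? gs * s : 0.0);
      const double drive = gL * EL + (use_sag ? gs * s * Eh : 0.0) -
                           w + I_inj + u;
      const double v_inf = drive / g_tot;
      v = v_inf + (v - v_inf) * std::exp(-dt * g_tot / C);
      if (v >= vth_eff) {
        spikes.push_back(i + 1);                  // 1-based sample index
        v = vreset;
        if (b > 0.0) w += b;
        ref_left = ref_steps;
        V[i] = vth_eff;                           // overwritten by stamp
        continue;
      }
    }
    if (!std::isfinite(v))
      stop("integration produced a non-finite membrane potential at sample %d", i + 1);
    V[i] = v;
  }

  return List::create(_["V"] = V, _["spike_idx"] = wrap(spikes));
}

// Sum of peak-normalised difference-of-exponential synaptic events.
// times_ms: event onset times; t is sampled at dt from t0_ms.
// [[Rcpp::export]]
NumericVector doe_events_cpp(int n, double t0_ms, double dt,
                             NumericVector times_ms, double amp,
                             double rise_ms, double decay_ms) {
  NumericVector out(n);
  const double tpk = std::log(decay_ms / rise_ms) * rise_ms * decay_ms /
                     (decay_ms - rise_ms);
  const double pk = std::exp(-tpk / decay_ms) - std::exp(-tpk / rise_ms);
  for (int k = 0; k < times_ms.size(); ++k) {
    const double te = times_ms[k];
    int i0 = (int) std::ceil((te - t0_ms) / dt);
    if (i0 < 0) i0 = 0;
    for (int i = i0; i < n; ++i) {
      const double t = t0_ms + i * dt - te;
      out[i] += amp / pk * (std::exp(-t / decay_ms) - std::exp(-t / rise_ms));
    }
  }
  return out;
}
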