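#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Core integration loop for a network of leaky integrate-and-fire neurons with
// alpha-function synaptic currents, transmission delays, injected and Gaussian
// noise currents.
//
// Units: time ms, voltage mV, current pA, resistance GOhm (mV = GOhm * pA).
//
// Per dt step:
//   1. deliver queued spike arrivals for this step into the kernel rise state
//   2. integrate the membrane (exponential Euler on the leak; exact for a
//      current held constant over the step), unless refractory
//   3. threshold crossing -> spike: reset, refractory, optionally clear the
//      neuron's synaptic kernel state (so only arrivals after its most
//      recent spike contribute), enqueue outgoing arrivals after their delays
//   4. decay the alpha-kernel states (exact two-state update)
//
// Refractory bookkeeping: after a spike a neuron is clamped for exactly t_ref
// and may fire again at the step ending t_ref after the spike, so a
// hard-driven neuron emits exactly 50 spikes in 100 ms at t_ref = 2 ms.
//
// The alpha kernel w * (t/tau) * exp(1 - t/tau) is generated by the linear
// system u' = -u/tau, g' = -g/tau + u with impulse u += w*e/tau; the exact
// step update is u <- u*E, g <- (g + dt*u)*E with E = exp(-dt/tau).

// [[Rcpp::export]]
List lif_run_cpp(NumericMatrix W, IntegerMatrix delay_steps,
                 NumericVector I_ext, double noise_sigma,
                 int n_steps, double dt,
                 double tau_m, double V_rest, double V_thres, double V_reset,
                 double R_m, double t_ref, double tau_syn,
                 List state, int bin_steps, int noise_steps,
                 bool clear_on_spike) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  const bool uniform_delay = (delay_steps.nrow() == 1 && delay_steps.ncol() == 1);

  int max_d = 1;
  if (uniform_delay) {
    max_d = delay_steps(0, 0);
    if (max_d < 1) stop("delays must be at least one step");
  } else {
    if (delay_steps.nrow() != n || delay_steps.ncol() != n)
      stop("delay matrix must match weight matrix");
    const int* dp = INTEGER(delay_steps);
    for (R_xlen_t k = 0; k < (R_xlen_t)n * n; ++k) {
      if (dp[k] < 1) stop("delays must be at least one step");
      if (dp[k] > max_d) max_d = dp[k];
    }
  }
  const int L = max_d + 1;

  NumericVector Vr = clone(as<NumericVector>(state["V"]));
  IntegerVector refr = clone(as<IntegerVector>(state["ref"]));
  NumericVector gr = clone(as<NumericVector>(state["g"]));
  NumericVector ghr = clone(as<NumericVector>(state["gh"]));
  if (Vr.size() != n || refr.size() != n || gr.size() != n || ghr.size() != n)
    stop("state vectors must have one entry per neuron");
  double* V = REAL(Vr);
  int* ref = INTEGER(refr);
  double* g = REAL(gr);
  double* gh = REAL(ghr);

  NumericMatrix bufr(n, L);  // ring buffer of future kernel-rise increments
  int buf_pos = 0;
  if (state.containsElementNamed("buf") && !Rf_isNull(state["buf"])) {
    NumericMatrix b0 = state["buf"];
    if (b0.nrow() == n && b0.ncol() == L) {
      bufr = clone(b0);
      buf_pos = as<int>(state["buf_pos"]);
    }
  }
  double* buf = REAL(bufr);

  const double* Wp = REAL(W);
  const double* Ie = REAL(I_ext);
  const int* dsp = INTEGER(delay_steps);
  const double E_m = std::exp(-dt / tau_m);
  const double RmI = R_m * (1.0 - E_m);
  const double E_s = std::exp(-dt / tau_syn);
  const double rise = std::exp(1.0) / tau_syn;  // impulse scaling: kernel peak = w
  const int ref_steps = (int)std::lround(t_ref / dt) - 1;
  if (ref_steps < 0) stop("dt must not exceed t_ref");

  const int n_bins = (n_steps + bin_steps - 1) / bin_steps;
  IntegerMatrix raster(n, n_bins);
  int* ras = INTEGER(raster);
  const bool noisy = noise_sigma > 0.0;
  if (noise_steps < 1) stop("noise interval must be at least one step");

  // noise current is redrawn every noise_steps steps and held in between
  // (piecewise-constant noise generator)
  std::vector<double> I_noise(n, 0.0);

  std::vector<int> fired;
  fired.reserve(n);

  for (int s = 0; s < n_steps; ++s) {
    // 1. deliver arrivals due now
    {
      double* col = buf + (R_xlen_t)n * buf_pos;
      for (int i = 0; i < n; ++i) {
        if (col[i] != 0.0) { gh[i] += col[i]; col[i] = 0.0; }
      }
    }

    // 2-3. membrane update and threshold
    fired.clear();
    if (noisy && s % noise_steps == 0)
      for (int i = 0; i < n; ++i) I_noise[i] = noise_sigma * norm_rand();
    const R_xlen_t bin_off = (R_xlen_t)n * (s / bin_steps);
    for (int i = 0; i < n; ++i) {
      if (ref[i] > 0) {
        ref[i]--;
        V[i] = V_reset;
        continue;
      }
      double I = Ie[i] + g[i];
      if (noisy) I += I_noise[i];
      V[i] = V_rest + (V[i] - V_rest) * E_m + RmI * I;
      if (V[i] > V_thres) {
        V[i] = V_reset;
        ref[i] = ref_steps;
        if (clear_on_spike) { g[i] = 0.0; gh[i] = 0.0; }
        ras[bin_off + i] = 1;
        fired.push_back(i);
      }
    }

    // 3b. enqueue outgoing arrivals of this step's spikes
    for (size_t f = 0; f < fired.size(); ++f) {
      const int j = fired[f];
      const double* wcol = Wp + (R_xlen_t)n * j;
      if (uniform_delay) {
        const int slot = (buf_pos + dsp[0]) % L;
        double* bcol = buf + (R_xlen_t)n * slot;
        for (int i = 0; i < n; ++i)
          bcol[i] += wcol[i] * rise;
      } else {
        const int* dcol = dsp + (R_xlen_t)n * j;
        for (int i = 0; i < n; ++i) {
          if (wcol[i] != 0.0) {
            const int slot = (buf_pos + dcol[i]) % L;
            buf[(R_xlen_t)n * slot + i] += wcol[i] * rise;
          }
        }
      }
    }

    // 4. exact alpha-kernel decay
    const double dtEs = dt * E_s;
    for (int i = 0; i < n; ++i) {
      g[i] = g[i] * E_s + gh[i] * dtEs;
      gh[i] *= E_s;
    }

    buf_pos = (buf_pos + 1) % L;
  }

  return List::create(
    _["raster"] = raster,
    _["state"] = List::create(_["V"] = Vr, _["ref"] = refr, _["g"] = gr,
                              _["gh"] = ghr, _["buf"] = bufr,
                              _["buf_pos"] = buf_pos));
}
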