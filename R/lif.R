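#' Leaky integrate-and-fire neuron parameters
#'
#' Bundles the membrane constants shared by every neuron in the network. The
#' defaults are the NEST-style values used throughout: membrane time constant
#' 10 ms, resting and reset potential -70 mV, threshold -55 mV, capacitance
#' 250 pF, absolute refractory period 2 ms, alpha-synapse rise time 2 ms. The
#' membrane resistance is derived as `R_m = tau_m / C_m` (10 ms / 250 pF =
#' 40 MOhm, stored in GOhm so that `R_m * I[pA]` is in mV).
#'
#' @param tau_m Membrane time constant (ms).
#' @param V_rest Resting potential (mV).
#' @param V_thres Spike threshold (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param C_m Membrane capacitance (pF).
#' @param t_ref Absolute refractory period (ms).
#' @param tau_syn Alpha-synapse rise time (ms).
#' @return An object of class `lif_params`.
#' @examples
#' p <- lif_params()
#' rheobase(p) # 375 pA
#' @export
lif_params <- function(tau_m = 10, V_rest = -70, V_thres = -55, V_reset = -70,
                       C_m = 250, t_ref = 2, tau_syn = 2) {
  if (tau_m <= 0 || C_m <= 0 || t_ref <= 0 || tau_syn <= 0)
    stop("tau_m, C_m, t_ref and tau_syn must be positive")
  if (!(V_reset <= V_rest && V_rest < V_thres))
    stop("require V_reset <= V_rest < V_thres")
  structure(
    list(tau_m = tau_m, V_rest = V_rest, V_thres = V_thres, V_reset = V_reset,
         C_m = C_m, t_ref = t_ref, tau_syn = tau_syn,
         R_m = tau_m / C_m), # GOhm
    class = "lif_params")
}

#' Rheobase current of a LIF neuron
#'
#' Minimal constant current that can ever bring the membrane to threshold,
#' `(V_thres - V_rest) / R_m`.
#'
#' @param params A [lif_params()] object.
#' @return Current in pA.
#' @export
rheobase <- function(params) {
  (params$V_thres - params$V_rest) / params$R_m
}

#' Alpha-function postsynaptic current kernel
#'
#' `alpha_psc(t) = (t / tau_syn) * exp(1 - t / tau_syn)` for `t >= 0`, zero
#' before the arrival. The kernel peaks at value 1 when `t = tau_syn`, so a
#' synaptic amplitude `w` (pA) yields a peak current of `w`.
#'
#' @param t Time since spike arrival (ms); vectorized.
#' @param tau_syn Rise time (ms).
#' @return Kernel values (unitless).
#' @examples
#' alpha_psc(2, tau_syn = 2) # 1
#' @export
alpha_psc <- function(t, tau_syn = 2) {
  if (tau_syn <= 0) stop("tau_syn must be positive")
  ifelse(t >= 0, t / tau_syn * exp(1 - t / tau_syn), 0)
}

#' Closed-form interspike interval under constant drive
#'
#' For a noise-free LIF neuron under constant suprathreshold current the
#' stationary interspike interval is
#' `t_ref + tau_m * log((R_m I + V_rest - V_reset) / (R_m I + V_rest - V_thres))`.
#' Used as an independent oracle for the simulator.
#'
#' @param params A [lif_params()] object.
#' @param I_const Injected current (pA), must exceed the rheobase.
#' @return Interspike interval (ms).
#' @export
analytic_isi <- function(params, I_const) {
  if (I_const <= rheobase(params))
    stop("current is at or below rheobase; the neuron never fires")
  RI <- params$R_m * I_const
  params$t_ref + params$tau_m *
    log((RI + params$V_rest - params$V_reset) / (RI + params$V_rest - params$V_thres))
}

#' Synapse matrix (amplitudes and delays)
#'
#' @param weights post x pre matrix of synaptic amplitudes (pA per presynaptic
#'   spike, peak of the alpha kernel).
#' @param delays Either a single delay (ms) applied to every synapse, or a
#'   post x pre matrix of delays.
#' @return An object of class `synapse_matrix`.
#' @export
synapse_matrix <- function(weights, delays = 1) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weight matrix must be square")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (is.matrix(delays) && !identical(dim(delays), dim(weights)))
    stop("delay matrix must match the weight matrix")
  if (any(delays <= 0)) stop("delays must be positive")
  structure(list(weights = weights, delays = delays), class = "synapse_matrix")
}

#' Fresh dynamic state for a LIF network
#'
#' All membranes at rest, no refractoriness, empty synaptic kernels and an
#' empty spike-arrival queue.
#'
#' @param n Number of neurons.
#' @param params A [lif_params()] object.
#' @return A state list consumed and returned by [simulate_lif()].
#' @export
network_state <- function(n, params = lif_params()) {
  list(V = rep(params$V_rest, n), ref = integer(n), g = numeric(n),
       gh = numeric(n), buf = NULL, buf_pos = 0L)
}

delays_in_steps <- function(synapses, dt) {
  d <- synapses$delays
  if (any(d < dt - 1e-9))
    stop("delays must be at least the simulation resolution")
  steps <- round(d / dt)
  if (any(abs(steps * dt - d) > 1e-9))
    stop("dt must divide all synaptic delays")
  if (is.matrix(d)) matrix(as.integer(steps), nrow(d), ncol(d))
  else matrix(as.integer(steps), 1, 1)
}

#' Simulate a LIF network
#'
#' Steps the whole network at resolution `dt` under a piecewise-constant
#' injection schedule, with i.i.d. Gaussian noise current redrawn per neuron
#' per step, and returns the spike raster binned at `dt_bin`.
#'
#' @param params A [lif_params()] object.
#' @param synapses A [synapse_matrix()] object.
#' @param schedule A list of segments `list(duration = ms, I_ext = per-neuron
#'   pA)`; the durations must tile the total simulated time.
#' @param noise_sigma Standard deviation of the noise current (pA).
#' @param noise_dt Interval (ms) at which the noise current is redrawn per
#'   neuron and held constant in between (piecewise-constant noise
#'   generator). Default 1 ms; at the default parameters this yields a
#'   subthreshold membrane fluctuation of a few mV, keeping undriven neurons
#'   in an irregular-firing regime once they receive synaptic input.
#' @param dt Integration step (ms); must divide `dt_bin`, all delays and all
#'   schedule durations, and must not exceed `t_ref`.
#' @param dt_bin Raster bin width (ms). With `dt_bin <= t_ref` each bin holds
#'   at most one spike per neuron.
#' @param seed Optional integer seed (wraps `set.seed`); the run is
#'   bit-reproducible given the seed and the initial state.
#' @param clear_on_spike If `TRUE`, a neuron's accumulated synaptic kernel
#'   state is zeroed whenever it fires, so only presynaptic arrivals after
#'   its most recent spike contribute current — the literal reading of the
#'   windowed synaptic sum. The default `FALSE` matches standard LIF
#'   simulators, whose alpha-function currents integrate across
#'   postsynaptic spikes.
#' @param state Optional state from a previous call, for continuing a run.
#' @param return_state If `TRUE`, also return the final network state.
#' @return A `spike_raster` (binary neurons x bins matrix with attributes
#'   `dt_bin` and `t0`), or `list(raster, state)` when `return_state` is set.
#' @export
simulate_lif <- function(params, synapses, schedule, noise_sigma = 0,
                         dt = 0.1, dt_bin = 1, noise_dt = 1, seed = NULL,
                         state = NULL, return_state = FALSE,
                         clear_on_spike = FALSE) {
  stopifnot(inherits(params, "lif_params"), inherits(synapses, "synapse_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(synapses$weights)
  if (is.null(state)) state <- network_state(n, params)
  if (dt > params$t_ref) stop("dt must not exceed t_ref")
  bin_steps <- round(dt_bin / dt)
  if (abs(bin_steps * dt - dt_bin) > 1e-9) stop("dt must divide dt_bin")
  noise_steps <- max(1L, as.integer(round(noise_dt / dt)))
  dmat <- delays_in_steps(synapses, dt)

  rasters <- list()
  for (seg in schedule) {
    dur <- seg$duration
    if (dur < 0) stop("schedule durations must be non-negative")
    if (dur == 0) next
    n_steps <- round(dur / dt)
    if (abs(n_steps * dt - dur) > 1e-9) stop("dt must divide schedule durations")
    I_ext <- rep_len(seg$I_ext, n)
    out <- lif_run_cpp(synapses$weights, dmat, I_ext, noise_sigma, n_steps, dt,
                       params$tau_m, params$V_rest, params$V_thres,
                       params$V_reset, params$R_m, params$t_ref,
                       params$tau_syn, state, as.integer(bin_steps),
                       noise_steps, isTRUE(clear_on_spike))
    state <- out$state
    rasters[[length(rasters) + 1L]] <- out$raster
  }
  spikes <- if (length(rasters)) do.call(cbind, rasters)
            else matrix(0L, n, 0)
  ras <- spike_raster(spikes, dt_bin = dt_bin, t0 = 0)
  if (return_state) list(raster = ras, state = state) else ras
}

#' Spike raster container
#'
#' @param spikes Binary neurons x bins matrix.
#' @param dt_bin Bin width (ms).
#' @param t0 Absolute start time of the first bin (ms).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, dt_bin = 1, t0 = 0) {
  spikes <- as.matrix(spikes)
  if (length(spikes) && !all(spikes %in% c(0L, 1L)))
    stop("raster entries must be 0 or 1")
  structure(spikes, dt_bin = dt_bin, t0 = t0, class = c("spike_raster", "matrix"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d bins (dt_bin = %g ms, t0 = %g ms), %d spikes\n",
              nrow(x), ncol(x), attr(x, "dt_bin"), attr(x, "t0"), sum(x)))
  invisible(x)
}

#' Subset a raster to its last `n` bins
#' @param raster A `spike_raster`.
#' @param n Number of trailing bins to keep.
#' @return A `spike_raster`.
#' @export
raster_tail <- function(raster, n) {
  nb <- ncol(raster)
  if (n > nb) stop("raster has fewer bins than requested")
  keep <- seq.int(nb - n + 1L, nb)
  spike_raster(unclass(raster)[, keep, drop = FALSE],
               dt_bin = attr(raster, "dt_bin"),
               t0 = attr(raster, "t0") + (nb - n) * attr(raster, "dt_bin"))
}

#' Mean firing indicator per neuron over a raster window
#'
#' The per-neuron fraction of bins containing a spike; with bins no longer
#' than the refractory period this is the per-bin firing probability that the
#' pseudo-free-energy estimators consume.
#'
#' @param raster A `spike_raster`.
#' @return Numeric vector in `[0, 1]`, one entry per neuron.
#' @export
firing_rates <- function(raster) {
  if (ncol(raster) == 0) stop("empty raster window")
  rowMeans(unclass(raster))
}
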