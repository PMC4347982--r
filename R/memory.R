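# Working-memory layer: fixed circular-Gaussian recurrent couplings that keep
# input-dependent activity bumps alive, and topographically constrained CD-3
# pretraining of the observation-to-memory couplings so different digits light
# up different positions on the memory ring.

#' Memory layer configuration
#'
#' Memory neurons sit at equally spaced positions on a circle. Recurrent
#' couplings follow `w[i,j] = g_s exp((cos(x_i - x_j) - 1) / g_w) - g_b`; the
#' default bias is `g_b = 0.1 g_s * integral_0^{2 pi} exp((cos x - 1)/g_w) dx`
#' (evaluated by adaptive quadrature), which balances the narrow excitatory
#' peak against a uniform inhibitory background.
#'
#' @param n_mem Number of memory neurons (default 50).
#' @param g_s Scaling factor (default 40).
#' @param g_w Width of the circular Gaussian (default `(pi/72)^2`).
#' @param g_b Bias term; `NULL` evaluates the default integral formula.
#' @return An object of class `memory_config`.
#' @export
memory_config <- function(n_mem = 50, g_s = 40, g_w = (pi / 72)^2, g_b = NULL) {
  if (n_mem < 2) stop("need at least two memory neurons")
  if (g_s <= 0 || g_w <= 0) stop("g_s and g_w must be positive")
  if (is.null(g_b))
    g_b <- 0.1 * g_s *
      stats::integrate(function(x) exp((cos(x) - 1) / g_w), 0, 2 * pi,
                       rel.tol = 1e-10)$value
  x <- 2 * pi * (seq_len(n_mem) - 1) / n_mem
  structure(list(n_mem = n_mem, g_s = g_s, g_w = g_w, g_b = g_b, x = x),
            class = "memory_config")
}

#' Circular-Gaussian recurrent weight matrix
#'
#' Symmetric circulant matrix with the entry formula of [memory_config()];
#' diagonal entries equal `g_s - g_b`.
#'
#' @param cfg A [memory_config()].
#' @return `n_mem x n_mem` numeric matrix.
#' @export
circular_gaussian_weights <- function(cfg) {
  d <- outer(cfg$x, cfg$x, "-")
  cfg$g_s * exp((cos(d) - 1) / cfg$g_w) - cfg$g_b
}

#' Circular neighborhood smoothing matrix
#'
#' Row-normalized circular-Gaussian kernel over the memory positions; applied
#' to hidden probabilities during CD statistics it correlates neighboring
#' units, the simplified topographic constraint used in pretraining.
#'
#' @param n_mem Number of memory neurons.
#' @param sigma Neighborhood width in radians (default `pi/12`).
#' @return Row-stochastic `n_mem x n_mem` matrix.
#' @export
neighborhood_smoother <- function(n_mem, sigma = pi / 12) {
  x <- 2 * pi * (seq_len(n_mem) - 1) / n_mem
  k <- exp((cos(outer(x, x, "-")) - 1) / sigma^2)
  k / rowSums(k)
}

#' Topographically constrained CD-3 pretraining of observation-to-memory
#' couplings
#'
#' Runs CD-k (default k = 3) with hidden activations smoothed over the memory
#' ring before the gradient statistics, so that features land at contiguous
#' map positions and distinct digit classes develop distinct modal positions
#' of memory activation.
#'
#' @param images Matrix with one flattened bitmap per row (values in
#'   `[0, 1]`, binarized at 0.5 internally).
#' @param n_mem Number of memory neurons.
#' @param neighborhood_sigma Smoothing width in radians.
#' @param lr Learning rate.
#' @param epochs Number of full passes.
#' @param k Gibbs steps per update (default 3).
#' @param seed Optional integer seed.
#' @return observation x memory coupling matrix, with attribute
#'   `recon_error_trace` (per-epoch mean squared reconstruction error).
#' @export
topographic_cd3_pretrain <- function(images, n_mem = 50,
                                     neighborhood_sigma = pi / 12,
                                     lr = 0.05, epochs = 50, k = 3,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  images <- as.matrix(images)
  v <- (images >= 0.5) * 1
  S <- neighborhood_smoother(n_mem, neighborhood_sigma)
  w <- matrix(rnorm(ncol(v) * n_mem, 0, 0.01), ncol(v), n_mem)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    w <- cd_k(w, v, k = k, lr = lr, smooth = S)
    trace[e] <- attr(w, "recon_error")
  }
  attr(w, "recon_error_trace") <- trace
  w
}

#' Modal memory position for an observation
#'
#' Circular mean of the memory posterior given a bitmap, used to check that
#' digit classes separate on the ring.
#'
#' @param w_mo observation x memory coupling matrix.
#' @param image Bitmap (matrix or flattened vector).
#' @return Angle in `[0, 2 pi)`.
#' @export
memory_peak_position <- function(w_mo, image) {
  p <- plogis(drop(crossprod(w_mo, as.numeric(image))))
  x <- 2 * pi * (seq_along(p) - 1) / length(p)
  atan2(sum(p * sin(x)), sum(p * cos(x))) %% (2 * pi)
}

#' Circular distance between two angles
#' @param a,b Angles in radians.
#' @return Distance in `[0, pi]`.
#' @export
circular_distance <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Observation-to-memory drive scaling
#'
#' Chooses the factor that turns the pretrained couplings into synaptic
#' amplitudes (pA) such that the most strongly driven memory neuron receives
#' a mean synaptic current of about `I_on` under the most effective training
#' image: excitatory inputs `sum_i v_i max(w_mo[i,j], 0)` times the
#' observation firing rate at `I_on` times the alpha-kernel charge
#' `e * tau_syn`.
#'
#' @param w_mo observation x memory coupling matrix.
#' @param images Matrix of flattened training bitmaps (one per row).
#' @param I_on Target peak current / observation injection (pA).
#' @param params A [lif_params()] object.
#' @return Scalar gain.
#' @export
memory_obs_gain <- function(w_mo, images, I_on = 2000, params = lif_params()) {
  rate <- 1 / analytic_isi(params, I_on)       # spikes per ms under I_on
  charge <- exp(1) * params$tau_syn            # integral of the alpha kernel
  drive <- as.matrix(images) %*% pmax(w_mo, 0) # per image x memory neuron
  I_on / (max(drive) * rate * charge)
}

#' Simulate the memory layer's spiking response to an observation sequence
#'
#' Wires observation neurons (one per pixel, driven by `pixel * I_on`) to the
#' memory ring through `w_mo` and the ring to itself through the
#' circular-Gaussian couplings, then runs the LIF network over a sequence of
#' observation segments. Used to inspect persistence of the activity bump
#' after input offset.
#'
#' @param w_mo observation x memory coupling matrix (drive scaled by
#'   `obs_gain`).
#' @param w_mm memory x memory recurrent matrix (scaled by `recurrent_gain`).
#' @param obs_seq List of segments `list(image = bitmap or NULL, duration =
#'   ms)`; `NULL` images mean no input.
#' @param I_on Injected current per fully-on pixel (pA).
#' @param noise_sigma Noise current s.d. (pA).
#' @param obs_gain,recurrent_gain Scaling of the two coupling blocks into
#'   synaptic pA amplitudes.
#' @param params,dt,noise_dt,seed Simulation controls.
#' @return A `spike_raster` over the memory neurons.
#' @export
memory_trace <- function(w_mo, w_mm, obs_seq, I_on = 2000, noise_sigma = 300,
                         obs_gain = 1, recurrent_gain = 1,
                         params = lif_params(), dt = 0.1, noise_dt = 1,
                         seed = NULL) {
  n_obs <- nrow(w_mo); n_mem <- ncol(w_mo)
  n <- n_obs + n_mem
  W <- matrix(0, n, n)
  mem_idx <- n_obs + seq_len(n_mem)
  W[mem_idx, seq_len(n_obs)] <- t(w_mo) * obs_gain
  W[mem_idx, mem_idx] <- w_mm * recurrent_gain
  schedule <- lapply(obs_seq, function(seg) {
    I <- numeric(n)
    if (!is.null(seg$image)) I[seq_len(n_obs)] <- as.numeric(seg$image) * I_on
    list(duration = seg$duration, I_ext = I)
  })
  ras <- simulate_lif(params, synapse_matrix(W), schedule,
                      noise_sigma = noise_sigma, dt = dt, noise_dt = noise_dt,
                      seed = seed)
  spike_raster(unclass(ras)[mem_idx, , drop = FALSE],
               dt_bin = attr(ras, "dt_bin"), t0 = attr(ras, "t0"))
}
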