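# Spike-based approximations of the RBM free energy.
#
# Three estimators of F(s_k, a_k) from spike data in the window preceding the
# next observation: the average-rate form (aFE) plugs window-mean firing
# indicators into the closed-form free energy; the batch instantaneous form
# (iFE) averages per-bin energies and adds the entropy term of the window-mean
# hidden rates; the sequential form tracks the same quantity online with two
# exponential filters so no spike train has to be stored.

xlogx <- function(x) ifelse(x <= 0, 0, x * log(x))

# sum_l [p log p + (1-p) log(1-p)] under the 0 log 0 = 0 convention
rate_entropy_term <- function(p) {
  if (any(p < 0 | p > 1)) stop("rates must lie in [0, 1]")
  sum(xlogx(p) + xlogx(1 - p))
}

#' Average-firing-rate pseudo-free-energy (aFE)
#'
#' Window-mean firing indicators replace the binary values everywhere in the
#' free-energy expression:
#' `-s_bar' w_sh h_bar - a_bar' w_ah h_bar + sum_l [h_bar log h_bar +
#' (1 - h_bar) log(1 - h_bar)]`.
#'
#' @param s_bar,a_bar,h_bar Per-neuron mean firing indicators over the window
#'   (values in `[0, 1]`).
#' @param W An [rbm_weights()] object.
#' @return Scalar pseudo-free-energy.
#' @export
afe <- function(s_bar, a_bar, h_bar, W) {
  check_config(s_bar, a_bar, W)
  if (length(h_bar) != ncol(W$w_sh)) stop("hidden rates do not match weights")
  if (any(c(s_bar, a_bar) < 0 | c(s_bar, a_bar) > 1))
    stop("rates must lie in [0, 1]")
  rbm_energy(s_bar, a_bar, h_bar, W) + rate_entropy_term(h_bar)
}

#' Batch average instantaneous pseudo-free-energy (iFE)
#'
#' Mean over the window's bins of the instantaneous energy
#' `E(s(t), a(t), h(t))` plus the entropy term evaluated at the window-mean
#' hidden rates. Unlike the aFE, per-bin coincidences between visible and
#' hidden spikes survive the averaging.
#'
#' @param s_spikes,a_spikes,h_spikes Binary neurons x bins matrices covering
#'   the same `N` bins (state/observation(+memory), action, hidden layers).
#' @param W An [rbm_weights()] object.
#' @return Scalar pseudo-free-energy.
#' @export
ife_batch <- function(s_spikes, a_spikes, h_spikes, W) {
  s_spikes <- as.matrix(s_spikes); a_spikes <- as.matrix(a_spikes)
  h_spikes <- as.matrix(h_spikes)
  N <- ncol(h_spikes)
  if (N < 1) stop("raster window is empty")
  if (ncol(s_spikes) != N || ncol(a_spikes) != N)
    stop("layer rasters must cover the same bins")
  if (nrow(s_spikes) != nrow(W$w_sh) || nrow(a_spikes) != nrow(W$w_ah) ||
      nrow(h_spikes) != ncol(W$w_sh)) stop("raster layers do not match weights")
  e_s <- colSums(crossprod(W$w_sh, s_spikes) * h_spikes)
  e_a <- colSums(crossprod(W$w_ah, a_spikes) * h_spikes)
  -mean(e_s + e_a) + rate_entropy_term(rowMeans(h_spikes))
}

#' Instantaneous free-energy sample for one bin
#'
#' `f(t) = E(s(t), a(t), h(t)) + sum_l [h_l(t) log h_hat_l +
#' (1 - h_l(t)) log(1 - h_hat_l)]`: the bin's energy plus the surprise of the
#' hidden spikes under the running probability estimate.
#'
#' @param s_t,a_t,h_t Binary spike vectors for one bin.
#' @param h_hat Running per-hidden firing probabilities (clamped internally to
#'   `[1e-12, 1 - 1e-12]` before the logs).
#' @param W An [rbm_weights()] object.
#' @return Scalar sample.
#' @export
f_inst <- function(s_t, a_t, h_t, h_hat, W) {
  eps <- 1e-12
  h_hat <- pmin(pmax(h_hat, eps), 1 - eps)
  rbm_energy(s_t, a_t, h_t, W) +
    sum(h_t * log(h_hat) + (1 - h_t) * log(1 - h_hat))
}

#' Initialize the sequential iFE estimator
#'
#' Running probabilities start at 1/2 (maximal uncertainty); the free-energy
#' filter is seeded with the first bin's sample on the first update.
#'
#' @param n_hidden Number of hidden neurons.
#' @param alpha_h,alpha_f Smoothing rates in `(0, 1]` for the hidden
#'   probability filter and the free-energy filter.
#' @return An object of class `fe_estimate`.
#' @export
fe_estimate <- function(n_hidden, alpha_h = 0.05, alpha_f = 0.05) {
  if (alpha_h <= 0 || alpha_h > 1 || alpha_f <= 0 || alpha_f > 1)
    stop("smoothing rates must lie in (0, 1]")
  structure(list(F_hat = NA_real_, h_hat = rep(0.5, n_hidden),
                 alpha_h = alpha_h, alpha_f = alpha_f, n_seen = 0L),
            class = "fe_estimate")
}

#' One step of the sequential iFE estimator
#'
#' Updates the running hidden probabilities toward the current bin's spikes,
#' computes the instantaneous sample [f_inst()] with the updated
#' probabilities, and low-pass filters it into the running estimate:
#' `h_hat <- h_hat + alpha_h (h - h_hat)`;
#' `F_hat <- F_hat + alpha_f (f - F_hat)`.
#'
#' @param est An [fe_estimate()].
#' @param s_t,a_t,h_t Binary spike vectors for the current bin.
#' @param W An [rbm_weights()] object.
#' @return The updated `fe_estimate`.
#' @export
ife_sequential_step <- function(est, s_t, a_t, h_t, W) {
  est$h_hat <- est$h_hat + est$alpha_h * (h_t - est$h_hat)
  f <- f_inst(s_t, a_t, h_t, est$h_hat, W)
  est$F_hat <- if (est$n_seen == 0L) f else est$F_hat + est$alpha_f * (f - est$F_hat)
  est$n_seen <- est$n_seen + 1L
  est
}

#' Run the sequential iFE estimator over a raster window
#'
#' @inheritParams ife_batch
#' @param alpha_h,alpha_f Smoothing rates.
#' @param est Optional estimator state to continue from.
#' @return The final `fe_estimate`; its `F_hat` field is the estimate.
#' @export
ife_sequential <- function(s_spikes, a_spikes, h_spikes, W,
                           alpha_h = 0.05, alpha_f = 0.05, est = NULL) {
  s_spikes <- as.matrix(s_spikes); a_spikes <- as.matrix(a_spikes)
  h_spikes <- as.matrix(h_spikes)
  if (is.null(est)) est <- fe_estimate(nrow(h_spikes), alpha_h, alpha_f)
  for (t in seq_len(ncol(h_spikes)))
    est <- ife_sequential_step(est, s_spikes[, t], a_spikes[, t],
                               h_spikes[, t], W)
  est
}
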