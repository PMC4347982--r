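#' RBM weights for free-energy-based reinforcement learning
#'
#' Couplings of the restricted Boltzmann machine whose negative free energy
#' approximates the state-action value function: a state (or observation, or
#' observation+memory) block `w_sh` and an action block `w_ah`, both undirected.
#'
#' @param w_sh state x hidden matrix.
#' @param w_ah action x hidden matrix (used identically in both directions).
#' @param w_mo Optional observation x memory matrix (pretrained, fixed).
#' @param w_mm Optional memory x memory matrix (fixed, recurrent).
#' @return An object of class `rbm_weights`.
#' @export
rbm_weights <- function(w_sh, w_ah, w_mo = NULL, w_mm = NULL) {
  w_sh <- as.matrix(w_sh); w_ah <- as.matrix(w_ah)
  if (ncol(w_sh) != ncol(w_ah)) stop("w_sh and w_ah must share the hidden dimension")
  if (any(!is.finite(w_sh)) || any(!is.finite(w_ah))) stop("weights must be finite")
  structure(list(w_sh = w_sh, w_ah = w_ah, w_mo = w_mo, w_mm = w_mm),
            class = "rbm_weights")
}

check_config <- function(s, a, W) {
  if (length(s) != nrow(W$w_sh)) stop("state vector does not match w_sh")
  if (length(a) != nrow(W$w_ah)) stop("action vector does not match w_ah")
}

#' RBM energy of a joint configuration
#'
#' `E(s, a, h) = - s' w_sh h - a' w_ah h`: every term couples a visible unit
#' (state or action) with a hidden unit; there are no within-layer couplings.
#'
#' @param s,a,h Binary (or rate-valued) vectors.
#' @param W An [rbm_weights()] object.
#' @return Scalar energy.
#' @export
rbm_energy <- function(s, a, h, W) {
  check_config(s, a, W)
  if (length(h) != ncol(W$w_sh)) stop("hidden vector does not match weights")
  -sum(crossprod(s, W$w_sh) * h) - sum(crossprod(a, W$w_ah) * h)
}

#' Posterior activation probabilities of the hidden units
#'
#' Because the RBM is bipartite the hidden units are conditionally independent
#' given the clamped visibles: `p(h_l = 1 | s, a) = sigmoid(sum_i w_sh(i,l) s_i
#' + sum_j w_ah(j,l) a_j)`.
#'
#' @inheritParams rbm_energy
#' @return Vector of probabilities, one per hidden unit.
#' @export
hidden_posterior <- function(s, a, W) {
  check_config(s, a, W)
  z <- drop(crossprod(W$w_sh, s)) + drop(crossprod(W$w_ah, a))
  plogis(z)
}

# entropy-like sum  sum_l [p log p + (1-p) log(1-p)]  with clamping
neg_entropy_term <- function(p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(p * log(p) + (1 - p) * log(1 - p))
}

#' Equilibrium free energy of a clamped RBM
#'
#' Expected energy minus entropy at equilibrium, available in closed form via
#' the hidden posterior:
#' `F(s, a) = -s' w_sh h_hat - a' w_ah h_hat + sum_l [h_hat log h_hat +
#' (1 - h_hat) log(1 - h_hat)]`, using the `0 log 0 = 0` convention
#' (probabilities clamped to `[eps, 1 - eps]`, `eps = 1e-12`). The negative
#' free energy is the model's state-action value.
#'
#' @inheritParams rbm_energy
#' @return Scalar free energy.
#' @export
free_energy <- function(s, a, W) {
  h_hat <- hidden_posterior(s, a, W)
  rbm_energy(s, a, h_hat, W) + neg_entropy_term(h_hat)
}

#' Softmax action selection for the exact RBM agent
#'
#' Samples an action from `softmax(beta * (-F(s, a_c)))` over the candidate
#' actions; `beta = Inf` takes the argmax of the value (argmin of F) with
#' uniform tie-breaking.
#'
#' @param s State vector.
#' @param W An [rbm_weights()] object.
#' @param actions List of candidate action vectors (e.g. one-hot codes).
#' @param beta Inverse temperature (>= 0, may be `Inf`).
#' @return Index of the selected action in `actions`.
#' @export
select_action_rbm <- function(s, W, actions, beta = 1) {
  if (length(actions) < 1) stop("need at least one candidate action")
  q <- vapply(actions, function(a) -free_energy(s, a, W), numeric(1))
  if (is.infinite(beta)) {
    best <- which(q >= max(q) - 1e-12)
    return(if (length(best) == 1) best else sample(best, 1))
  }
  z <- beta * q
  p <- exp(z - max(z)); p <- p / sum(p)
  sample.int(length(actions), 1, prob = p)
}

#' One SARSA transition
#'
#' A `(s_k, a_k, r, s_next, a_next)` tuple, optionally carrying the spiking
#' agent's rate statistics (window-mean firing indicators and measured free
#' energies) that replace the binary visibles in the rate-based update.
#'
#' @param s,a Current state and action vectors.
#' @param r Reward received after executing `a`.
#' @param s_next,a_next Next state and action vectors (`NULL` when terminal).
#' @param terminal Logical; terminal transitions drop the discounted term.
#' @param rates Optional list with `s_bar`, `a_bar`, `h_bar` (current step),
#'   `F`, `F_next` (estimator values) from the spiking agent.
#' @return An object of class `ferl_transition`.
#' @export
ferl_transition <- function(s, a, r, s_next = NULL, a_next = NULL,
                            terminal = FALSE, rates = NULL) {
  if (!is.finite(r)) stop("reward must be finite")
  structure(list(s = s, a = a, r = r, s_next = s_next, a_next = a_next,
                 terminal = terminal, rates = rates),
            class = "ferl_transition")
}

#' SARSA update of the RBM couplings
#'
#' Temporal-difference learning on the negative free energy: with
#' `delta = r - gamma * F(s', a') + F(s, a)` (the `gamma` term dropped on
#' terminal transitions), each coupling moves along the gradient of `-F`:
#' `w_sh(i,l) += alpha * delta * s_i * h_hat_l` and
#' `w_ah(j,l) += alpha * delta * a_j * h_hat_l`, with the posterior evaluated
#' at `(s, a)`. A positive surprise lowers `F(s, a)` so the action is favored
#' next time; a negative surprise raises it.
#'
#' @param W An [rbm_weights()] object.
#' @param tr A [ferl_transition()].
#' @param gamma Discount factor in `[0, 1]`.
#' @param alpha Learning rate (> 0).
#' @return The updated [rbm_weights()], with attribute `delta` (the TD error).
#' @export
sarsa_update <- function(W, tr, gamma = 0.99, alpha = 1e-5) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (alpha <= 0) stop("alpha must be positive")
  F_sa <- free_energy(tr$s, tr$a, W)
  delta <- if (tr$terminal) tr$r + F_sa
           else tr$r - gamma * free_energy(tr$s_next, tr$a_next, W) + F_sa
  h_hat <- hidden_posterior(tr$s, tr$a, W)
  W$w_sh <- W$w_sh + alpha * delta * tcrossprod(tr$s, h_hat)
  W$w_ah <- W$w_ah + alpha * delta * tcrossprod(tr$a, h_hat)
  attr(W, "delta") <- delta
  W
}

#' Contrastive-divergence (CD-k) step for a visible-hidden RBM
#'
#' Standard CD-k on a minibatch of binary visible vectors: positive-phase
#' statistics `v h_hat(v)` minus the statistics of the k-step Gibbs
#' reconstruction. Used for pretraining observation-to-memory couplings.
#'
#' @param w visible x hidden coupling matrix.
#' @param minibatch Matrix with one visible vector per row.
#' @param k Number of Gibbs steps (>= 1).
#' @param lr Learning rate.
#' @param smooth Optional hidden x hidden smoothing matrix applied to the
#'   hidden probabilities before the gradient statistics (the topographic
#'   constraint); `NULL` for plain CD.
#' @return Updated coupling matrix, with attribute `recon_error` (mean squared
#'   reconstruction error of the minibatch).
#' @export
cd_k <- function(w, minibatch, k = 1, lr = 0.01, smooth = NULL) {
  if (k < 1) stop("k must be at least 1")
  minibatch <- as.matrix(minibatch)
  if (nrow(minibatch) < 1) stop("empty minibatch")
  if (ncol(minibatch) != nrow(w)) stop("visible dimension mismatch")
  nb <- nrow(minibatch)
  ph_data <- plogis(minibatch %*% w)
  v <- minibatch
  ph <- ph_data
  for (step in seq_len(k)) {
    h <- matrix(rbinom(length(ph), 1, ph), nrow(ph), ncol(ph))
    pv <- plogis(tcrossprod(h, w))
    v <- matrix(rbinom(length(pv), 1, pv), nrow(pv), ncol(pv))
    ph <- plogis(v %*% w)
  }
  pos_h <- ph_data; neg_h <- ph
  if (!is.null(smooth)) { pos_h <- pos_h %*% smooth; neg_h <- neg_h %*% smooth }
  grad <- (crossprod(minibatch, pos_h) - crossprod(v, neg_h)) / nb
  out <- w + lr * grad
  attr(out, "recon_error") <- mean((minibatch - pv)^2)
  out
}
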