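# The spiking FERL agent: wires state/observation (+ optional memory), hidden
# and action LIF populations, runs 1000 ms observation/action cycles, selects
# actions by comparing action-block spike counts, measures the pseudo-free-
# energy over the last 100 ms of the action phase, and applies the rate-based
# SARSA update to the couplings (which double as the synaptic amplitudes).

#' Agent configuration
#'
#' Layer sizes, injected currents, cycle timing and learning settings for one
#' task. Presets follow the task conventions: 90/484/300 state or observation
#' neurons for the plain maze, the digit maze and the T-maze respectively; 90
#' hidden and 90 action neurons everywhere; 50 memory neurons in the T-maze;
#' injected current 1000 pA with -2000 pA suppression and noise s.d. 600 pA in
#' the reaching tasks, 2000 / -5000 / 300 pA in the T-maze. A cycle is 1000 ms
#' (500 ms observation phase + 500 ms action phase); the pseudo-free-energy
#' and the rate statistics come from the last `N = 100` bins (1 ms each) of
#' the action phase.
#'
#' @param task `"center"`, `"digit_center"` or `"tmaze"`.
#' @param n_state,n_hidden,n_action,n_mem Layer sizes.
#' @param I_on Excitatory injection to active code neurons (pA).
#' @param I_off Suppressive injection to non-selected action neurons during
#'   the action phase (pA).
#' @param noise_sigma Noise current s.d. (pA).
#' @param noise_dt Interval (ms) at which the noise current is redrawn and
#'   held (default 1 ms).
#' @param clear_on_spike Whether a neuron's synaptic kernel state is zeroed
#'   at its own spikes (see [simulate_lif()]); default `FALSE`.
#' @param obs_ms,act_ms Phase durations (ms).
#' @param gamma Discount factor.
#' @param alpha TD learning rate.
#' @param estimator `"ife_batch"`, `"afe"` or `"ife_seq"`.
#' @param dt Integration step (ms).
#' @param dt_bin Raster bin (ms); must not exceed the refractory period.
#' @param N Estimator window in bins.
#' @param alpha_h,alpha_f Sequential-estimator smoothing rates.
#' @param select_window Bins of the observation phase counted for action
#'   selection (its last 100 ms).
#' @param delay Synaptic delay (ms) applied to all synapses.
#' @param randomize_delays If `TRUE`, redraw per-synapse delays uniformly in
#'   `[0.5, 5]` ms at each episode (the delay-randomization experiment).
#' @param episode_cap Maximum cycles per episode.
#' @param w_init_mean,w_init_sd Initial coupling distribution (N(20, 11.88^2)).
#' @param obs_gain,recurrent_gain T-maze scaling of the fixed
#'   observation-to-memory and memory-to-memory synapses.
#' @param params A [lif_params()] object.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(task = c("center", "digit_center", "tmaze"),
                         n_state = NULL, n_hidden = 90, n_action = 90,
                         n_mem = NULL, I_on = NULL, I_off = NULL,
                         noise_sigma = NULL, noise_dt = 1, clear_on_spike = FALSE,
                         obs_ms = 500, act_ms = 500,
                         gamma = 0.99, alpha = 7e-4,
                         estimator = c("ife_batch", "afe", "ife_seq"),
                         dt = 0.1, dt_bin = 1, N = 100,
                         alpha_h = 0.05, alpha_f = 0.05,
                         select_window = 100, delay = 1,
                         randomize_delays = FALSE, episode_cap = NULL,
                         w_init_mean = 20, w_init_sd = 11.88,
                         obs_gain = 1, recurrent_gain = 1,
                         params = lif_params()) {
  task <- match.arg(task)
  estimator <- match.arg(estimator)
  if (is.null(n_state))
    n_state <- switch(task, center = 90L, digit_center = 484L, tmaze = 300L)
  if (is.null(n_mem)) n_mem <- if (task == "tmaze") 50L else 0L
  if (is.null(I_on)) I_on <- if (task == "tmaze") 2000 else 1000
  if (is.null(I_off)) I_off <- if (task == "tmaze") -5000 else -2000
  if (is.null(noise_sigma)) noise_sigma <- if (task == "tmaze") 300 else 600
  if (is.null(episode_cap)) episode_cap <- if (task == "tmaze") 10L else 50L
  if (min(n_state, n_hidden, n_action) < 1) stop("layer sizes must be positive")
  if (n_action %% 2 != 0) stop("action layer must split into two equal blocks")
  if (obs_ms + act_ms <= 0) stop("cycle must have positive duration")
  if (gamma < 0 || gamma > 1 || alpha <= 0) stop("invalid gamma or alpha")
  structure(list(task = task, n_state = as.integer(n_state),
                 n_hidden = as.integer(n_hidden),
                 n_action = as.integer(n_action), n_mem = as.integer(n_mem),
                 I_on = I_on, I_off = I_off, noise_sigma = noise_sigma,
                 noise_dt = noise_dt, clear_on_spike = clear_on_spike,
                 obs_ms = obs_ms, act_ms = act_ms, gamma = gamma,
                 alpha = alpha, estimator = estimator, dt = dt,
                 dt_bin = dt_bin, N = as.integer(N), alpha_h = alpha_h,
                 alpha_f = alpha_f, select_window = as.integer(select_window),
                 delay = delay, randomize_delays = randomize_delays,
                 episode_cap = as.integer(episode_cap),
                 w_init_mean = w_init_mean, w_init_sd = w_init_sd,
                 obs_gain = obs_gain, recurrent_gain = recurrent_gain,
                 params = params),
            class = "agent_config")
}

#' Population code of an agent
#'
#' Maps discrete state and action labels to contiguous neuron index blocks.
#' The 90 state neurons of the plain maze split into 7 contiguous blocks of
#' sizes 13, 13, 13, 12, 13, 13, 13; the 90 action neurons split into two
#' halves (`left` = 1..45, `right` = 46..90) in every task.
#'
#' @param cfg An [agent_config()].
#' @return List with `state_blocks` (for the plain maze) and `action_blocks`
#'   (indices within the action layer).
#' @export
population_code <- function(cfg) {
  state_blocks <- NULL
  if (cfg$task == "center") {
    sizes <- c(13, 13, 13, 12, 13, 13, 13)
    stopifnot(sum(sizes) == cfg$n_state)
    ends <- cumsum(sizes)
    state_blocks <- lapply(seq_along(sizes), function(i)
      seq.int(ends[i] - sizes[i] + 1L, ends[i]))
    names(state_blocks) <- 0:6
  }
  half <- cfg$n_action / 2
  action_blocks <- list(left = seq_len(half),
                        right = seq.int(half + 1L, cfg$n_action))
  list(state_blocks = state_blocks, action_blocks = action_blocks)
}

#' Build a spiking FERL agent
#'
#' Draws the couplings from `N(w_init_mean, w_init_sd^2)` (defaults 20 and
#' 11.88, chosen so initial weights are mostly positive and the network sits
#' in a normal firing regime). State/observation (and memory) neurons project
#' unidirectionally to hidden neurons; action and hidden neurons are
#' bidirectionally connected with symmetric weights. For the T-maze the fixed
#' observation-to-memory couplings `w_mo` (pretrained) and the circular
#' Gaussian ring `w_mm` are attached; the memory block counts as part of the
#' RBM's state layer, so its couplings to hidden are learned like the rest.
#'
#' @param cfg An [agent_config()].
#' @param seed Optional integer seed for the weight draw.
#' @param w_mo,w_mm T-maze fixed couplings (e.g. from
#'   [topographic_cd3_pretrain()] and [circular_gaussian_weights()]).
#' @param gain_images Optional matrix of flattened training bitmaps; when
#'   given with `w_mo`, the observation-to-memory gain is set with
#'   [memory_obs_gain()] so the peak memory drive is comparable to `I_on`.
#' @return An object of class `snn_agent`.
#' @export
build_agent <- function(cfg, seed = NULL, w_mo = NULL, w_mm = NULL,
                        gain_images = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(gain_images) && !is.null(w_mo))
    cfg$obs_gain <- memory_obs_gain(w_mo, gain_images, cfg$I_on, cfg$params)
  n_sl <- cfg$n_state + cfg$n_mem  # RBM state layer: observation + memory
  w_sh <- matrix(rnorm(n_sl * cfg$n_hidden, cfg$w_init_mean, cfg$w_init_sd),
                 n_sl, cfg$n_hidden)
  w_ah <- matrix(rnorm(cfg$n_action * cfg$n_hidden, cfg$w_init_mean,
                       cfg$w_init_sd), cfg$n_action, cfg$n_hidden)
  if (cfg$n_mem > 0) {
    if (is.null(w_mm)) w_mm <- circular_gaussian_weights(memory_config(cfg$n_mem))
    if (is.null(w_mo)) stop("the T-maze agent needs pretrained w_mo couplings")
    if (nrow(w_mo) != cfg$n_state || ncol(w_mo) != cfg$n_mem)
      stop("w_mo must be n_state x n_mem")
  }
  n <- n_sl + cfg$n_hidden + cfg$n_action
  layout <- list(
    obs = seq_len(cfg$n_state),
    mem = if (cfg$n_mem > 0) cfg$n_state + seq_len(cfg$n_mem) else integer(0),
    state = seq_len(n_sl),
    hidden = n_sl + seq_len(cfg$n_hidden),
    action = n_sl + cfg$n_hidden + seq_len(cfg$n_action),
    n = n)
  structure(list(cfg = cfg,
                 W = rbm_weights(w_sh, w_ah, w_mo = w_mo, w_mm = w_mm),
                 code = population_code(cfg), layout = layout,
                 delays = cfg$delay,
                 net_state = network_state(n, cfg$params)),
            class = "snn_agent")
}

# Couplings -> synaptic amplitude matrix (post x pre, pA). The RBM weights are
# used directly as amplitudes; the action-hidden block appears transposed on
# both sides of the bidirectional connection, so it stays symmetric under any
# number of TD updates.
assemble_synapses <- function(agent) {
  cfg <- agent$cfg; lay <- agent$layout
  W <- matrix(0, lay$n, lay$n)
  W[lay$hidden, lay$state] <- t(agent$W$w_sh)
  W[lay$hidden, lay$action] <- t(agent$W$w_ah)
  W[lay$action, lay$hidden] <- agent$W$w_ah
  if (cfg$n_mem > 0) {
    W[lay$mem, lay$obs] <- t(agent$W$w_mo) * cfg$obs_gain
    W[lay$mem, lay$mem] <- agent$W$w_mm * cfg$recurrent_gain
  }
  synapse_matrix(W, delays = agent$delays)
}

# observation -> per-observation-neuron drive in [0, 1]
obs_drive <- function(agent, obs) {
  cfg <- agent$cfg
  if (cfg$task == "center") {
    d <- numeric(cfg$n_state)
    d[agent$code$state_blocks[[as.character(obs)]]] <- 1
    d
  } else {
    as.numeric(obs)
  }
}

#' Per-neuron injected current for one phase
#'
#' Observation phase: active state/observation neurons receive `I_on` (scaled
#' by pixel intensity for bitmaps); action neurons receive no injection, so
#' their activity reflects hidden-layer feedback plus noise. Action phase: the
#' state drive stays on, the selected action block receives `I_on` and all
#' other action neurons the suppressive `I_off`.
#'
#' @param agent An [build_agent()] object.
#' @param drive Per-observation-neuron drive in `[0, 1]`.
#' @param phase `"observation"` or `"action"`.
#' @param action Selected action label (required in the action phase).
#' @return Numeric vector of injected currents (pA), one per neuron.
#' @export
injection_schedule <- function(agent, drive, phase = c("observation", "action"),
                               action = NULL) {
  phase <- match.arg(phase)
  cfg <- agent$cfg; lay <- agent$layout
  I <- numeric(lay$n)
  I[lay$obs] <- drive * cfg$I_on
  if (phase == "action") {
    if (is.null(action)) stop("the action phase needs a selected action")
    I[lay$action] <- cfg$I_off
    I[lay$action[agent$code$action_blocks[[action]]]] <- cfg$I_on
  }
  I
}

#' Select an action from action-layer spike counts
#'
#' Returns the label of the action block with the larger total spike count
#' over the counting window; exact ties are broken uniformly at random.
#'
#' @param raster A `spike_raster` over the action layer (rows = action
#'   neurons).
#' @param action_blocks Named list of index blocks within the raster rows.
#' @param window Number of trailing bins to count (default: all).
#' @return The selected label.
#' @export
select_action_spikes <- function(raster, action_blocks, window = NULL) {
  if (length(action_blocks) < 2) stop("need at least two action blocks")
  m <- unclass(raster)
  if (!is.null(window)) m <- unclass(raster_tail(raster, window))
  if (ncol(m) == 0) stop("empty counting window")
  counts <- vapply(action_blocks, function(idx) sum(m[idx, , drop = FALSE]),
                   numeric(1))
  best <- which(counts == max(counts))
  names(action_blocks)[if (length(best) == 1) best else sample(best, 1)]
}

#' Measure the pseudo-free-energy of a raster window
#'
#' Dispatches to the configured estimator: [afe()] on the window-mean rates,
#' [ife_batch()] on the per-bin spikes, or the sequential filter
#' [ife_sequential()] run across the window.
#'
#' @param agent An agent.
#' @param s_spikes,a_spikes,h_spikes Layer rasters over the window (matrices).
#' @return Scalar pseudo-free-energy.
#' @export
measure_fe <- function(agent, s_spikes, a_spikes, h_spikes) {
  cfg <- agent$cfg
  switch(cfg$estimator,
    afe = afe(rowMeans(s_spikes), rowMeans(a_spikes), rowMeans(h_spikes),
              agent$W),
    ife_batch = ife_batch(s_spikes, a_spikes, h_spikes, agent$W),
    ife_seq = ife_sequential(s_spikes, a_spikes, h_spikes, agent$W,
                             alpha_h = cfg$alpha_h,
                             alpha_f = cfg$alpha_f)$F_hat)
}

#' Run one observation/action cycle
#'
#' Simulates the observation phase (state drive on, action layer free),
#' selects an action from the action-block spike counts over the phase's last
#' 100 ms, simulates the action phase (state drive on, selected block driven,
#' the rest suppressed), measures the pseudo-free-energy and the layer rate
#' statistics over the last `N` bins of the action phase, and steps the
#' environment.
#'
#' @param agent An agent (its network state is advanced).
#' @param env The environment (after [env_reset()]).
#' @param keep_rasters If `TRUE`, attach the full phase rasters.
#' @return List with the updated `agent` and `env`, the chosen `action`,
#'   measured `F`, rate statistics `s_bar`/`a_bar`/`h_bar`, `reward`, `done`,
#'   `capped`, and the observed `state_label`.
#' @export
run_cycle <- function(agent, env, keep_rasters = FALSE) {
  cfg <- agent$cfg; lay <- agent$layout
  # each discrete step is conditionally independent given its clamped state
  # and action, so the cycle starts from quiescence; carrying the
  # hidden/action attractor state across cycles makes spike-count selection
  # hysteretic (it re-elects the previous winner) instead of value-driven
  agent$net_state <- network_state(lay$n, cfg$params)
  obs <- env_observe(env)
  state_label <- if (cfg$task == "center") env$pos else attr(obs, "class_label")
  drive <- obs_drive(agent, obs)
  syn <- assemble_synapses(agent)

  out1 <- simulate_lif(cfg$params, syn,
                       list(list(duration = cfg$obs_ms,
                                 I_ext = injection_schedule(agent, drive, "observation"))),
                       noise_sigma = cfg$noise_sigma, dt = cfg$dt,
                       dt_bin = cfg$dt_bin, noise_dt = cfg$noise_dt,
                       clear_on_spike = cfg$clear_on_spike,
                       state = agent$net_state, return_state = TRUE)
  agent$net_state <- out1$state
  act_raster_obs <- spike_raster(unclass(out1$raster)[lay$action, , drop = FALSE],
                                 dt_bin = cfg$dt_bin)
  action <- select_action_spikes(act_raster_obs, agent$code$action_blocks,
                                 window = min(cfg$select_window, ncol(act_raster_obs)))

  out2 <- simulate_lif(cfg$params, syn,
                       list(list(duration = cfg$act_ms,
                                 I_ext = injection_schedule(agent, drive, "action", action))),
                       noise_sigma = cfg$noise_sigma, dt = cfg$dt,
                       dt_bin = cfg$dt_bin, noise_dt = cfg$noise_dt,
                       clear_on_spike = cfg$clear_on_spike,
                       state = agent$net_state, return_state = TRUE)
  agent$net_state <- out2$state
  win <- unclass(raster_tail(out2$raster, cfg$N))
  s_spk <- win[lay$state, , drop = FALSE]
  a_spk <- win[lay$action, , drop = FALSE]
  h_spk <- win[lay$hidden, , drop = FALSE]
  F_hat <- measure_fe(agent, s_spk, a_spk, h_spk)

  step <- env_step(env, action)
  res <- list(agent = agent, env = step$env, action = action, F = F_hat,
              s_bar = rowMeans(s_spk), a_bar = rowMeans(a_spk),
              h_bar = rowMeans(h_spk), reward = step$reward,
              done = step$done, capped = step$capped,
              state_label = state_label)
  if (keep_rasters) {
    res$obs_raster <- out1$raster
    res$act_raster <- out2$raster
  }
  res
}

#' Rate-based SARSA update of the couplings
#'
#' The spiking analogue of [sarsa_update()]: binary visibles and the exact
#' posterior are replaced by the measured window-mean firing indicators, and
#' the free energies by the spike-based estimates. `delta = r - gamma F_next +
#' F` (terminal steps drop the discounted term), `w_sh += alpha delta
#' outer(s_bar, h_bar)`, `w_ah += alpha delta outer(a_bar, h_bar)`.
#'
#' @param W An [rbm_weights()] object.
#' @param tr A [ferl_transition()] whose `rates` field carries `s_bar`,
#'   `a_bar`, `h_bar`, `F` and (unless terminal) `F_next`.
#' @param gamma,alpha Discount factor and learning rate.
#' @return Updated weights, with attribute `delta`.
#' @export
td_update_rates <- function(W, tr, gamma = 0.99, alpha = 1e-5) {
  r <- tr$rates
  if (is.null(r)) stop("transition carries no rate statistics")
  delta <- if (tr$terminal) tr$r + r$F else tr$r - gamma * r$F_next + r$F
  W$w_sh <- W$w_sh + alpha * delta * tcrossprod(r$s_bar, r$h_bar)
  W$w_ah <- W$w_ah + alpha * delta * tcrossprod(r$a_bar, r$h_bar)
  attr(W, "delta") <- delta
  W
}

#' Train a spiking FERL agent
#'
#' Runs repeated episodes of observation/action cycles with one TD update per
#' transition (each update waits for the next cycle's free-energy estimate;
#' terminal transitions are updated immediately without the discounted term).
#' Membrane and synaptic state are reset at each episode start; when
#' `randomize_delays` is set, per-synapse delays are redrawn uniformly in
#' `[0.5, 5]` ms at each episode.
#'
#' @param agent A [build_agent()] object.
#' @param env A matching [ferl_env()].
#' @param episodes Number of episodes (>= 1).
#' @param seed Optional integer seed making the whole run reproducible.
#' @param keep_weights If `TRUE`, store a weight snapshot every
#'   `snapshot_every` episodes.
#' @param snapshot_every Episodes between snapshots.
#' @return An object of class `ferl_fit`: the trained `agent`, a per-episode
#'   tibble `log` (cycles, steps to goal, summed and discounted reward, mean
#'   TD error, mean measured F), and metadata.
#' @export
train_agent <- function(agent, env, episodes, seed = NULL,
                        keep_weights = FALSE, snapshot_every = 50) {
  if (episodes < 1) stop("need at least one episode")
  if (!is.null(seed)) set.seed(seed)
  cfg <- agent$cfg
  log <- vector("list", episodes)
  snapshots <- list()
  for (ep in seq_len(episodes)) {
    env <- env_reset(env)
    agent$net_state <- network_state(agent$layout$n, cfg$params)
    if (cfg$randomize_delays) {
      n <- agent$layout$n
      agent$delays <- matrix(round(runif(n * n, 0.5, 5) / cfg$dt) * cfg$dt, n, n)
    }
    prev <- NULL
    reward_sum <- 0; disc_return <- 0; deltas <- c(); F_trace <- c()
    goal_steps <- NA_integer_
    for (k in seq_len(cfg$episode_cap)) {
      out <- run_cycle(agent, env)
      agent <- out$agent; env <- out$env
      reward_sum <- reward_sum + out$reward
      disc_return <- disc_return + cfg$gamma^(k - 1) * out$reward
      F_trace <- c(F_trace, out$F)
      if (!is.null(prev)) {
        tr <- ferl_transition(NULL, NULL, prev$reward, terminal = FALSE,
                              rates = list(s_bar = prev$s_bar, a_bar = prev$a_bar,
                                           h_bar = prev$h_bar, F = prev$F,
                                           F_next = out$F))
        agent$W <- td_update_rates(agent$W, tr, cfg$gamma, cfg$alpha)
        deltas <- c(deltas, attr(agent$W, "delta"))
      }
      if (out$done) {
        if (!out$capped) {
          tr <- ferl_transition(NULL, NULL, out$reward, terminal = TRUE,
                                rates = list(s_bar = out$s_bar, a_bar = out$a_bar,
                                             h_bar = out$h_bar, F = out$F))
          agent$W <- td_update_rates(agent$W, tr, cfg$gamma, cfg$alpha)
          deltas <- c(deltas, attr(agent$W, "delta"))
          goal_steps <- k
        }
        break
      }
      prev <- out
    }
    log[[ep]] <- tibble::tibble(
      episode = ep, cycles = env$step, steps_to_goal = goal_steps,
      reward_sum = reward_sum, discounted_return = disc_return,
      mean_delta = if (length(deltas)) mean(deltas) else NA_real_,
      mean_F = mean(F_trace))
    if (keep_weights && (ep %% snapshot_every == 0 || ep == episodes))
      snapshots[[as.character(ep)]] <- agent$W
  }
  structure(list(agent = agent, log = dplyr::bind_rows(log),
                 episodes = episodes, seed = seed,
                 estimator = cfg$estimator, task = cfg$task,
                 snapshots = snapshots),
            class = "ferl_fit")
}

#' @export
print.ferl_fit <- function(x, ...) {
  cat(sprintf("<ferl_fit> %s task, %s estimator, %d episodes\n",
              x$task, x$estimator, x$episodes))
  tail_n <- min(50L, x$episodes)
  tl <- utils::tail(x$log, tail_n)
  cat(sprintf("  median steps to goal (last %d episodes): %s\n", tail_n,
              format(stats::median(tl$steps_to_goal, na.rm = TRUE))))
  cat(sprintf("  median discounted return (last %d episodes): %s\n", tail_n,
              format(stats::median(tl$discounted_return))))
  invisible(x)
}

#' Evaluate a trained agent without learning
#'
#' Runs greedy (spike-count) episodes with the weights frozen.
#'
#' @param agent A trained agent (e.g. `fit$agent`).
#' @param env A matching environment.
#' @param episodes Number of evaluation episodes.
#' @param seed Optional integer seed.
#' @return A tibble with one row per episode.
#' @export
evaluate_agent <- function(agent, env, episodes = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- agent$cfg
  rows <- vector("list", episodes)
  for (ep in seq_len(episodes)) {
    env <- env_reset(env)
    agent$net_state <- network_state(agent$layout$n, cfg$params)
    reward_sum <- 0; disc_return <- 0; goal_steps <- NA_integer_
    for (k in seq_len(cfg$episode_cap)) {
      out <- run_cycle(agent, env)
      agent <- out$agent; env <- out$env
      reward_sum <- reward_sum + out$reward
      disc_return <- disc_return + cfg$gamma^(k - 1) * out$reward
      if (out$done) { if (!out$capped) goal_steps <- k; break }
    }
    rows[[ep]] <- tibble::tibble(episode = ep, cycles = env$step,
                                 steps_to_goal = goal_steps,
                                 reward_sum = reward_sum,
                                 discounted_return = disc_return)
  }
  dplyr::bind_rows(rows)
}
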