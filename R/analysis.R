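# Evaluation analyses relating the trained spiking network to its RBM
# counterpart: spike-count vs free-energy action preference, free-energy
# equivalence under weight scaling with shuffle controls, firing-pattern
# distance matrices, and PCA of hidden activations.

#' One-hot code over the state layer for a discrete state
#' @param agent A center-reaching agent.
#' @param s State label (0..6).
#' @return Binary vector over the state layer.
#' @export
state_onehot <- function(agent, s) {
  v <- numeric(agent$cfg$n_state + agent$cfg$n_mem)
  v[agent$code$state_blocks[[as.character(s)]]] <- 1
  v
}

#' One-hot code over the action layer for an action label
#' @param agent An agent.
#' @param action `"left"` or `"right"`.
#' @return Binary vector over the action layer.
#' @export
action_onehot <- function(agent, action) {
  v <- numeric(agent$cfg$n_action)
  v[agent$code$action_blocks[[action]]] <- 1
  v
}

#' Probe an agent with a bare state injection
#'
#' Injects a state's code for `ms` milliseconds (no action drive) from a
#' fresh network state and returns the action-block and hidden spike counts.
#'
#' @param agent An agent.
#' @param s State label (or bitmap for digit tasks).
#' @param ms Injection duration (ms).
#' @return List with `action_counts` (named per block) and `hidden_counts`.
#' @export
probe_state <- function(agent, s, ms = 100) {
  cfg <- agent$cfg; lay <- agent$layout
  syn <- assemble_synapses(agent)
  drive <- obs_drive(agent, s)
  ras <- simulate_lif(cfg$params, syn,
                      list(list(duration = ms,
                                I_ext = injection_schedule(agent, drive, "observation"))),
                      noise_sigma = cfg$noise_sigma, dt = cfg$dt,
                      dt_bin = cfg$dt_bin, noise_dt = cfg$noise_dt,
                      clear_on_spike = cfg$clear_on_spike,
                      state = network_state(lay$n, cfg$params))
  m <- unclass(ras)
  list(action_counts = vapply(agent$code$action_blocks,
                              function(idx) sum(m[lay$action[idx], , drop = FALSE]),
                              numeric(1)),
       hidden_counts = rowSums(m[lay$hidden, , drop = FALSE]))
}

#' Probe an agent with a clamped state-action pair
#'
#' Clamps a state-action pair under action-phase injections from a fresh
#' network state, discards `warmup` ms, and measures the batch iFE, the
#' hidden spike counts and the layer rasters over the last `N` bins.
#'
#' @param agent An agent.
#' @param s State label (or bitmap for digit tasks).
#' @param action `"left"` or `"right"`.
#' @param warmup Discarded settling time (ms).
#' @return List with `F` (batch iFE), `hidden_counts`, `rates`, and the
#'   window `rasters` per layer.
#' @export
probe_state_action <- function(agent, s, action, warmup = 100) {
  cfg <- agent$cfg; lay <- agent$layout
  syn <- assemble_synapses(agent)
  drive <- obs_drive(agent, s)
  I <- injection_schedule(agent, drive, "action", action)
  ras <- simulate_lif(cfg$params, syn,
                      list(list(duration = warmup + cfg$N * cfg$dt_bin, I_ext = I)),
                      noise_sigma = cfg$noise_sigma, dt = cfg$dt,
                      dt_bin = cfg$dt_bin, noise_dt = cfg$noise_dt,
                      clear_on_spike = cfg$clear_on_spike,
                      state = network_state(lay$n, cfg$params))
  win <- unclass(raster_tail(ras, cfg$N))
  s_spk <- win[lay$state, , drop = FALSE]
  a_spk <- win[lay$action, , drop = FALSE]
  h_spk <- win[lay$hidden, , drop = FALSE]
  list(F = ife_batch(s_spk, a_spk, h_spk, agent$W),
       hidden_counts = rowSums(h_spk),
       rates = list(s = rowMeans(s_spk), a = rowMeans(a_spk),
                    h = rowMeans(h_spk)),
       rasters = list(state = spike_raster(s_spk, dt_bin = cfg$dt_bin),
                      action = spike_raster(a_spk, dt_bin = cfg$dt_bin),
                      hidden = spike_raster(h_spk, dt_bin = cfg$dt_bin)))
}

#' Spike-count vs free-energy action preference
#'
#' For each state, injects its code for 100 ms and records the left/right
#' action-block spike counts, then clamps each state-action pair and measures
#' the negative instantaneous pseudo-free-energy. The per-state left-minus-
#' right differences of the two quantities are correlated (Pearson) across
#' states: a high correlation means spike-count action selection reflects the
#' learned values.
#'
#' @param agent A trained center-reaching agent.
#' @param states States to probe (default 0..6).
#' @param probe_ms Injection duration for the counting probe (ms).
#' @param reps Probe repetitions averaged per state (counts) and per
#'   state-action pair (iFE); more repetitions reduce measurement noise.
#' @param seed Optional integer seed.
#' @return List with `r` (the correlation) and `data` (per-state tibble).
#' @export
action_preference_correlation <- function(agent, states = 0:6, probe_ms = 100,
                                          reps = 1, seed = NULL) {
  if (length(states) < 3) stop("need at least three states")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(states, function(s) {
    cc <- rowMeans(replicate(reps, probe_state(agent, s, ms = probe_ms)$action_counts))
    fl <- mean(replicate(reps, probe_state_action(agent, s, "left")$F))
    fr <- mean(replicate(reps, probe_state_action(agent, s, "right")$F))
    tibble::tibble(state = s,
                   count_left = cc[["left"]],
                   count_right = cc[["right"]],
                   neg_ife_left = -fl, neg_ife_right = -fr)
  })
  data <- dplyr::bind_rows(rows)
  d_counts <- data$count_left - data$count_right
  d_fe <- data$neg_ife_left - data$neg_ife_right
  list(r = stats::cor(d_counts, d_fe), data = data)
}

#' Free-energy equivalence between the SNN and its RBM counterpart
#'
#' Builds the equivalent RBM from the agent's own couplings divided by the
#' scaling coefficient `c` (default 1000; spiking networks need large weights
#' to stay in a firing regime, the RBM does not), computes its exact negative
#' free energy and hidden posterior for every state-action pair under clamped
#' one-hot codes, and compares them with the spiking network's measured
#' negative iFE and hidden spike counts. Optionally repeats the posterior
#' comparison after shuffling the state-hidden and action-hidden couplings
#' independently (the control under which the correlation should collapse).
#'
#' @param agent A trained center-reaching agent.
#' @param c Weight scaling coefficient (> 0).
#' @param shuffle `"none"` or `"independent"`.
#' @param n_shuffles Number of shuffles averaged in the control.
#' @param states States to probe.
#' @param seed Optional integer seed.
#' @return An object of class `fe_equivalence`: per-pair tibble `data`,
#'   `r_fe` (negative iFE vs RBM negative F over pairs), `r_posterior` (mean
#'   over pairs of the count/posterior correlation across hidden neurons),
#'   `r_posterior_shuffled` (mean over shuffles, `NA` unless requested),
#'   `degenerate` flag, and `c`.
#' @export
fe_equivalence <- function(agent, c = 1000, shuffle = c("none", "independent"),
                           n_shuffles = 20, states = 0:6, seed = NULL) {
  shuffle <- match.arg(shuffle)
  if (c <= 0) stop("the scaling coefficient must be positive")
  if (!is.null(seed)) set.seed(seed)
  actions <- c("left", "right")
  W_rbm <- rbm_weights(agent$W$w_sh / c, agent$W$w_ah / c)

  rows <- list(); counts <- list(); posts <- list()
  for (s in states) for (a in actions) {
    pr <- probe_state_action(agent, s, a)
    sv <- state_onehot(agent, s); av <- action_onehot(agent, a)
    key <- paste(s, a)
    counts[[key]] <- pr$hidden_counts
    posts[[key]] <- hidden_posterior(sv, av, W_rbm)
    rows[[key]] <- tibble::tibble(
      state = s, action = a, neg_ife = -pr$F,
      neg_F_rbm = -free_energy(sv, av, W_rbm),
      r_posterior = safe_cor(pr$hidden_counts, posts[[key]]))
  }
  data <- dplyr::bind_rows(rows)
  degenerate <- stats::sd(data$neg_ife) == 0 || stats::sd(data$neg_F_rbm) == 0
  r_fe <- if (degenerate) NA_real_ else stats::cor(data$neg_ife, data$neg_F_rbm)

  r_shuf <- NA_real_
  if (shuffle == "independent") {
    per_shuffle <- vapply(seq_len(n_shuffles), function(i) {
      Ws <- rbm_weights(
        matrix(sample(agent$W$w_sh), nrow(agent$W$w_sh)) / c,
        matrix(sample(agent$W$w_ah), nrow(agent$W$w_ah)) / c)
      mean(vapply(states, function(s) {
        mean(vapply(actions, function(a) {
          p <- hidden_posterior(state_onehot(agent, s), action_onehot(agent, a), Ws)
          safe_cor(counts[[paste(s, a)]], p)
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    r_shuf <- mean(per_shuffle)
  }
  structure(list(data = data, r_fe = r_fe,
                 r_posterior = mean(data$r_posterior, na.rm = TRUE),
                 r_posterior_shuffled = r_shuf,
                 degenerate = degenerate, c = c),
            class = "fe_equivalence")
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' @export
print.fe_equivalence <- function(x, ...) {
  cat(sprintf("<fe_equivalence> c = %g\n", x$c))
  cat(sprintf("  -iFE vs RBM -F correlation: %s\n", format(x$r_fe)))
  cat(sprintf("  hidden count vs posterior correlation (mean): %s\n",
              format(x$r_posterior)))
  if (!is.na(x$r_posterior_shuffled))
    cat(sprintf("  shuffled-weight control: %s\n", format(x$r_posterior_shuffled)))
  if (x$degenerate) cat("  (degenerate: constant free energies)\n")
  invisible(x)
}

#' Firing-pattern distance matrix and dominant periodicity
#'
#' Pairwise normalized Hamming distance between the population spike vectors
#' of each pair of bins (equivalently squared Euclidean distance on 0/1
#' vectors divided by the neuron count), plus the lag (>= 2 bins) minimizing
#' the mean distance -- the dominant periodicity of recurring firing
#' patterns.
#'
#' @param raster A `spike_raster` (e.g. the hidden layer over the last
#'   100 ms).
#' @param metric `"hamming"` or `"euclidean"` (on the raw values).
#' @param max_lag Largest lag inspected (default 20).
#' @return List with the `distance` matrix, a `lag_profile` tibble and the
#'   dominant `period`.
#' @export
pattern_distance <- function(raster, metric = c("hamming", "euclidean"),
                             max_lag = 20) {
  metric <- match.arg(metric)
  m <- unclass(raster)
  nb <- ncol(m)
  if (nb < 2) stop("need at least two bins")
  D <- as.matrix(stats::dist(t(m), method = "euclidean"))
  if (metric == "hamming") D <- D^2 / nrow(m)
  lags <- 2:min(max_lag, nb - 1)
  prof <- vapply(lags, function(l) {
    idx <- seq_len(nb - l)
    mean(D[cbind(idx, idx + l)])
  }, numeric(1))
  list(distance = D,
       lag_profile = tibble::tibble(lag = lags, mean_distance = prof),
       period = lags[which.min(prof)])
}

#' PCA of labelled hidden-activation vectors
#'
#' Centered principal component analysis of hidden rate (or count) vectors,
#' returning 2-D projections with their condition labels and the explained
#' variance ratios.
#'
#' @param X samples x neurons matrix.
#' @param labels Optional per-sample labels.
#' @return List with `scores` (tibble: PC1, PC2, label), `explained`
#'   (variance ratios summing to 1), and a `degenerate` flag for constant
#'   data.
#' @export
hidden_pca <- function(X, labels = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two samples")
  tot <- sum(apply(X, 2, stats::var))
  if (tot == 0)
    return(list(scores = NULL, explained = NULL, degenerate = TRUE))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  if (!is.null(labels)) scores$label <- labels
  list(scores = scores, explained = expl, degenerate = FALSE)
}

#' Mean silhouette score of a labelling
#'
#' Euclidean silhouette averaged over samples; used to compare how well
#' hidden activations cluster by one labelling versus another.
#'
#' @param X samples x features matrix.
#' @param labels Per-sample labels (>= 2 distinct, each with >= 2 samples).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X); labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least two label groups")
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    if (!length(same)) return(0)
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Hidden-layer activations of an agent across probe conditions
#'
#' Clamps each requested state-action pair and returns the hidden rate
#' vectors, for use with [hidden_pca()] or [silhouette_score()].
#'
#' @param agent A trained agent.
#' @param conditions Tibble or data.frame with columns `state` and `action`;
#'   for digit tasks `state` may be repeated to sample observation variants.
#' @param env Environment supplying observations for digit tasks (`NULL` for
#'   the plain maze).
#' @param seed Optional integer seed.
#' @return Tibble with `state`, `action` and one column per hidden neuron.
#' @export
hidden_activations <- function(agent, conditions, env = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    s <- conditions$state[i]; a <- conditions$action[i]
    obs <- if (agent$cfg$task == "center") s
           else digit_sample(env$digit_bank, s)
    pr <- probe_state_action_obs(agent, obs, a)
    tibble::tibble(state = s, action = a,
                   !!!stats::setNames(as.list(pr$rates$h),
                                      paste0("h", seq_along(pr$rates$h))))
  })
  dplyr::bind_rows(rows)
}

# like probe_state_action but takes a raw observation (bitmap or state label)
probe_state_action_obs <- function(agent, obs, action, warmup = 100) {
  cfg <- agent$cfg; lay <- agent$layout
  syn <- assemble_synapses(agent)
  drive <- obs_drive(agent, obs)
  I <- injection_schedule(agent, drive, "action", action)
  ras <- simulate_lif(cfg$params, syn,
                      list(list(duration = warmup + cfg$N * cfg$dt_bin, I_ext = I)),
                      noise_sigma = cfg$noise_sigma, dt = cfg$dt,
                      dt_bin = cfg$dt_bin, noise_dt = cfg$noise_dt,
                      clear_on_spike = cfg$clear_on_spike,
                      state = network_state(lay$n, cfg$params))
  win <- unclass(raster_tail(ras, cfg$N))
  list(rates = list(s = rowMeans(win[lay$state, , drop = FALSE]),
                    a = rowMeans(win[lay$action, , drop = FALSE]),
                    h = rowMeans(win[lay$hidden, , drop = FALSE])))
}
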