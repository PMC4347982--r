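test_that("configuration presets follow the task conventions", {
  c1 <- agent_config("center")
  expect_equal(c(c1$n_state, c1$n_hidden, c1$n_action, c1$n_mem),
               c(90L, 90L, 90L, 0L))
  expect_equal(c(c1$I_on, c1$I_off, c1$noise_sigma), c(1000, -2000, 600))
  expect_equal(c1$obs_ms + c1$act_ms, 1000)
  c2 <- agent_config("digit_center")
  expect_equal(c2$n_state, 484L)  # 22 x 22
  c3 <- agent_config("tmaze")
  expect_equal(c(c3$n_state, c3$n_hidden, c3$n_mem, c3$n_action),
               c(300L, 90L, 50L, 90L))
  expect_equal(c(c3$I_on, c3$I_off, c3$noise_sigma), c(2000, -5000, 300))
  expect_error(agent_config("center", n_hidden = 0), "positive")
})

test_that("population codes are disjoint, contiguous and split actions in halves", {
  code <- population_code(agent_config("center"))
  blocks <- code$state_blocks
  expect_length(blocks, 7)
  expect_equal(vapply(blocks, length, integer(1)),
               c(`0` = 13L, `1` = 13L, `2` = 13L, `3` = 12L, `4` = 13L,
                 `5` = 13L, `6` = 13L))
  expect_equal(unname(sort(unlist(blocks))), 1:90)
  for (b in blocks) expect_equal(b, seq(min(b), max(b)))
  expect_equal(code$action_blocks$left, 1:45)
  expect_equal(code$action_blocks$right, 46:90)
})

test_that("agent builds are seed-reproducible with the stated weight statistics", {
  cfg <- agent_config("center")
  a1 <- build_agent(cfg, seed = 3)
  a2 <- build_agent(cfg, seed = 3)
  expect_identical(a1$W, a2$W)
  # CLT bound on the mean of 90 x 90 N(20, 11.88^2) draws
  expect_lt(abs(mean(a1$W$w_sh) - 20), 3 * 11.88 / 90)
  expect_equal(sd(a1$W$w_sh), 11.88, tolerance = 0.05)
  # T-maze build has the Table-1 layer sizes and fixed memory couplings
  w_mo <- matrix(0.1, 300, 50)
  a3 <- build_agent(agent_config("tmaze"), seed = 3, w_mo = w_mo)
  expect_equal(a3$layout$n, 300 + 50 + 90 + 90)
  expect_equal(dim(a3$W$w_sh), c(350L, 90L))
  expect_equal(dim(a3$W$w_mm), c(50L, 50L))
  expect_error(build_agent(agent_config("tmaze"), seed = 3), "w_mo")
})

test_that("the synapse matrix keeps the action-hidden block symmetric", {
  agent <- build_agent(agent_config("center"), seed = 5)
  syn <- assemble_synapses(agent)$weights
  lay <- agent$layout
  expect_equal(syn[lay$action, lay$hidden], t(syn[lay$hidden, lay$action]))
  # state -> hidden is unidirectional
  expect_true(all(syn[lay$state, ] == 0))
  # and it stays symmetric after TD updates with rate statistics
  W2 <- td_update_rates(agent$W,
                        ferl_transition(NULL, NULL, 1000, terminal = TRUE,
                                        rates = list(s_bar = runif(90),
                                                     a_bar = runif(90),
                                                     h_bar = runif(90),
                                                     F = -500)),
                        gamma = 0.99, alpha = 1e-4)
  agent$W <- W2
  syn2 <- assemble_synapses(agent)$weights
  expect_equal(syn2[lay$action, lay$hidden], t(syn2[lay$hidden, lay$action]))
})

test_that("injected currents follow the phase protocol", {
  agent <- build_agent(agent_config("center"), seed = 6)
  drive <- obs_drive(agent, 2)
  lay <- agent$layout
  I_obs <- injection_schedule(agent, drive, "observation")
  # active state block at I_on, all action neurons undriven
  expect_equal(unique(I_obs[lay$state[agent$code$state_blocks[["2"]]]]), 1000)
  expect_true(all(I_obs[lay$action] == 0))
  expect_true(all(I_obs[lay$hidden] == 0))
  I_act <- injection_schedule(agent, drive, "action", "right")
  right <- lay$action[agent$code$action_blocks$right]
  left <- lay$action[agent$code$action_blocks$left]
  expect_equal(unique(I_act[right]), 1000)
  expect_equal(unique(I_act[left]), -2000)
  expect_error(injection_schedule(agent, drive, "action"), "selected action")
  # T-maze currents
  a3 <- build_agent(agent_config("tmaze"), seed = 3,
                    w_mo = matrix(0.1, 300, 50))
  I3 <- injection_schedule(a3, rep(1, 300), "action", "left")
  expect_equal(unique(I3[a3$layout$action[a3$code$action_blocks$left]]), 2000)
  expect_equal(unique(I3[a3$layout$action[a3$code$action_blocks$right]]), -5000)
})

test_that("spike-count action selection takes the larger block with fair ties", {
  blocks <- list(left = 1:3, right = 4:6)
  m <- matrix(0L, 6, 10)
  m[1, 1:5] <- 1L; m[4, 1] <- 1L
  expect_equal(select_action_spikes(spike_raster(m), blocks), "left")
  # agreement with a naive argmax oracle on random rasters
  set.seed(404)
  for (i in 1:20) {
    r <- matrix(rbinom(60, 1, 0.3), 6, 10)
    counts <- c(sum(r[1:3, ]), sum(r[4:6, ]))
    if (counts[1] == counts[2]) next
    expect_equal(select_action_spikes(spike_raster(r), blocks),
                 c("left", "right")[which.max(counts)])
  }
  # exact ties break uniformly
  tie <- matrix(0L, 6, 4); tie[1, 1] <- 1L; tie[4, 2] <- 1L
  picks <- replicate(1000, select_action_spikes(spike_raster(tie), blocks))
  expect_equal(mean(picks == "left"), 0.5, tolerance = 0.06)
  expect_error(select_action_spikes(spike_raster(matrix(0L, 6, 0)), blocks),
               "empty")
})

test_that("rate-based TD update reproduces the stated arithmetic", {
  # single coupling, delta = 2, s_bar = 0.5, h_bar = 0.25, alpha = 0.1
  W <- rbm_weights(matrix(0), matrix(0))
  tr <- ferl_transition(NULL, NULL, r = 2, terminal = TRUE,
                        rates = list(s_bar = 0.5, a_bar = 0, h_bar = 0.25,
                                     F = 0))
  W2 <- td_update_rates(W, tr, gamma = 0.99, alpha = 0.1)
  expect_equal(attr(W2, "delta"), 2)
  expect_equal(W2$w_sh[1, 1], 0.1 * 2 * 0.5 * 0.25)
  # with all rates 1 it matches the binary SARSA update exactly
  set.seed(405)
  Wb <- random_rbm(3, 2, 4)
  s <- rep(1, 3); a <- rep(1, 2)
  F_sa <- free_energy(s, a, Wb)
  h_hat <- hidden_posterior(s, a, Wb)
  tr_bin <- ferl_transition(s, a, r = 7, terminal = TRUE)
  W_bin <- sarsa_update(Wb, tr_bin, gamma = 0.9, alpha = 1e-3)
  # rate route: h_bar set to the posterior, F to the exact free energy
  tr_rate <- ferl_transition(NULL, NULL, r = 7, terminal = TRUE,
                             rates = list(s_bar = s, a_bar = a, h_bar = h_hat,
                                          F = F_sa))
  W_rate <- td_update_rates(Wb, tr_rate, gamma = 0.9, alpha = 1e-3)
  expect_equal(W_rate$w_sh, W_bin$w_sh)
  expect_equal(W_rate$w_ah, W_bin$w_ah)
  # zero TD error changes nothing
  tr0 <- ferl_transition(NULL, NULL, r = -F_sa, terminal = TRUE,
                         rates = list(s_bar = s, a_bar = a, h_bar = h_hat,
                                      F = F_sa))
  W0 <- td_update_rates(Wb, tr0, 0.9, 1e-3)
  expect_equal(W0$w_sh, Wb$w_sh)
  expect_error(td_update_rates(Wb, ferl_transition(NULL, NULL, 1)), "rate")
})

test_that("a full cycle is reproducible and produces coherent measurements", {
  cfg <- agent_config("center")
  agent <- build_agent(cfg, seed = 7)
  env <- ferl_env("center")
  set.seed(7); env1 <- env_reset(env)
  out1 <- run_cycle(agent, env1)
  set.seed(7); env2 <- env_reset(env)
  out2 <- run_cycle(agent, env2)
  expect_identical(out1$action, out2$action)
  expect_identical(out1$F, out2$F)
  expect_identical(out1$h_bar, out2$h_bar)
  # rates are proper firing fractions and active state neurons fire in the
  # regime the parameters imply (about 15 spikes per 100 ms at 1000 pA)
  expect_true(all(out1$s_bar >= 0 & out1$s_bar <= 0.5))
  active <- agent$code$state_blocks[[as.character(out1$state_label)]]
  expect_equal(mean(out1$s_bar[active]) * 100, 100 / analytic_isi(cfg$params, 1000),
               tolerance = 0.25)
  # suppressed action block fires far less than the selected one
  sel <- agent$code$action_blocks[[out1$action]]
  other <- setdiff(1:90, sel)
  expect_lt(mean(out1$a_bar[other]), mean(out1$a_bar[sel]) / 3)
  expect_gt(mean(out1$a_bar[sel]), 0.1)
})

test_that("training without learning (alpha -> 0 surrogate) leaves behavior stationary", {
  # alpha must be positive; an effectively-zero rate freezes the weights
  cfg <- agent_config("center", alpha = 1e-300, episode_cap = 6)
  agent <- build_agent(cfg, seed = 8)
  env <- ferl_env("center")
  fit <- train_agent(agent, env, episodes = 2, seed = 8)
  expect_equal(fit$agent$W$w_sh, agent$W$w_sh, tolerance = 1e-20)
  expect_equal(nrow(fit$log), 2)
  expect_error(train_agent(agent, env, episodes = 0), "at least one")
  # tidiers return the expected shapes
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
})
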