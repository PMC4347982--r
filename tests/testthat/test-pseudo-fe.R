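test_that("aFE reduces to the closed-form free energy under matching rates", {
  set.seed(201)
  W <- random_rbm(4, 2, 6)
  # all rates zero: zero energy and zero entropy under 0 log 0 = 0
  expect_equal(afe(numeric(4), numeric(2), numeric(6), W), 0)
  # saturated 0/1 rates equal direct substitution into the energy (entropy
  # vanishes at 0/1)
  s <- rbinom(4, 1, 0.5); a <- c(1, 0); h <- rbinom(6, 1, 0.5)
  expect_equal(afe(s, a, h, W), naive_energy(s, a, h, W))
  # plugging the exact posterior reproduces the closed-form free energy
  hb <- hidden_posterior(s, a, W)
  expect_equal(afe(s, a, hb, W), free_energy(s, a, W))
  expect_error(afe(c(0.5, 2), numeric(2), numeric(6), random_rbm(2, 2, 6)),
               "\\[0, 1\\]")
})

test_that("batch iFE matches the naive per-bin loop oracle", {
  set.seed(202)
  for (i in 1:10) {
    W <- random_rbm(3, 2, 5)
    N <- 20
    s_spk <- bernoulli_raster(runif(3), N)
    a_spk <- bernoulli_raster(runif(2), N)
    h_spk <- bernoulli_raster(runif(5), N)
    expect_equal(ife_batch(s_spk, a_spk, h_spk, W),
                 naive_ife(s_spk, a_spk, h_spk, W), tolerance = 1e-12)
  }
  # empty (all-zero) raster gives 0
  W <- random_rbm(3, 2, 5)
  z <- matrix(0L, 3, 10)
  expect_equal(ife_batch(z, matrix(0L, 2, 10), matrix(0L, 5, 10), W), 0)
  expect_error(ife_batch(z[, 0], matrix(0L, 2, 0), matrix(0L, 5, 0), W),
               "empty")
})

test_that("aFE and batch iFE coincide on windows with constant per-bin patterns", {
  set.seed(203)
  W <- random_rbm(4, 2, 6)
  s <- rbinom(4, 1, 0.5); a <- rbinom(2, 1, 0.5); h <- rbinom(6, 1, 0.5)
  N <- 17
  s_spk <- matrix(s, 4, N); a_spk <- matrix(a, 2, N); h_spk <- matrix(h, 6, N)
  expect_equal(ife_batch(s_spk, a_spk, h_spk, W),
               afe(rowMeans(s_spk), rowMeans(a_spk), rowMeans(h_spk), W))
})

test_that("instantaneous sample matches an independent loop and guards its logs", {
  set.seed(204)
  W <- random_rbm(3, 2, 5)
  s <- rbinom(3, 1, 0.5); a <- rbinom(2, 1, 0.5); h <- rbinom(5, 1, 0.5)
  h_hat <- runif(5, 0.2, 0.8)
  manual <- naive_energy(s, a, h, W) +
    sum(h * log(h_hat) + (1 - h) * log(1 - h_hat))
  expect_equal(f_inst(s, a, h, h_hat, W), manual)
  # no spikes anywhere at h_hat = 1/2: H * ln(1/2)
  expect_equal(f_inst(numeric(3), numeric(2), numeric(5), rep(0.5, 5), W),
               5 * log(0.5))
  # certain events carry no surprise: h_hat -> 0/1 limits with matching spikes
  expect_equal(f_inst(numeric(3), numeric(2), c(1, 1, 0, 0, 0),
                      c(1, 1, 0, 0, 0), W),
               0, tolerance = 1e-9)
  # unclamped 0/1 probabilities with mismatched spikes stay finite
  expect_true(is.finite(f_inst(numeric(3), numeric(2), c(1, 0, 0, 0, 0),
                               c(0, 1, 1, 1, 1), W)))
})

test_that("sequential filter tracks its inputs as specified", {
  W <- random_rbm(2, 2, 3)
  # alpha_h = 1 makes h_hat equal the instantaneous spikes
  est <- fe_estimate(3, alpha_h = 1, alpha_f = 0.5)
  h <- c(1, 0, 1)
  est <- ife_sequential_step(est, c(0, 0), c(0, 0), h, W)
  expect_equal(est$h_hat, h)
  # after a nonzero start, an all-zero spike stream (whose samples are ~0
  # once h_hat has tracked the silence) decays F_hat geometrically at rate
  # 1 - alpha_f
  W0 <- rbm_weights(matrix(1, 1, 2), matrix(0, 1, 2))
  est0 <- fe_estimate(2, alpha_h = 1, alpha_f = 0.25)
  est0 <- ife_sequential_step(est0, 1, 0, c(1, 1), W0)  # seeds F_hat at -2
  vals <- numeric(40)
  for (t in 1:40) {
    est0 <- ife_sequential_step(est0, 1, 0, c(0, 0), W0)
    vals[t] <- est0$F_hat
  }
  ratio <- vals[10:30] / vals[9:29]
  expect_equal(ratio, rep(0.75, 21), tolerance = 1e-6)
  expect_lt(abs(vals[40]), 1e-4)
  expect_error(fe_estimate(2, alpha_h = 0), "\\(0, 1\\]")
})

test_that("sequential estimate agrees with the batch estimator on stationary rasters", {
  set.seed(205)
  W <- random_rbm(4, 2, 8)
  s <- rbinom(4, 1, 0.5); a <- c(1, 0)
  p_h <- runif(8, 0.2, 0.8)
  N <- 400
  seq_vals <- batch_vals <- numeric(60)
  for (r in 1:60) {
    s_spk <- matrix(s, 4, N)
    a_spk <- matrix(a, 2, N)
    h_spk <- bernoulli_raster(p_h, N)
    batch_vals[r] <- ife_batch(s_spk, a_spk, h_spk, W)
    seq_vals[r] <- ife_sequential(s_spk, a_spk, h_spk, W,
                                  alpha_h = 0.05, alpha_f = 0.05)$F_hat
  }
  se <- sd(seq_vals - batch_vals) / sqrt(60)
  expect_lt(abs(mean(seq_vals) - mean(batch_vals)), 3 * max(se, 1e-12) + 0.5)
})

test_that("batch iFE converges to the exact free energy for posterior-driven spikes", {
  # with hidden spikes i.i.d. Bernoulli(posterior), the iFE is an unbiased
  # estimate of F up to the entropy sampling error, which shrinks with N
  set.seed(206)
  W <- random_rbm(3, 2, 6)
  s <- c(1, 0, 1); a <- c(1, 0)
  p <- hidden_posterior(s, a, W)
  F_true <- free_energy(s, a, W)
  err_at <- function(N, reps = 40) {
    mean(replicate(reps, {
      h_spk <- bernoulli_raster(p, N)
      abs(ife_batch(matrix(s, 3, N), matrix(a, 2, N), h_spk, W) - F_true)
    }))
  }
  errs <- vapply(c(50, 200, 800), err_at, numeric(1))
  # error decreases with window length, roughly as 1/sqrt(N)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  slope <- coef(lm(log(errs) ~ log(c(50, 200, 800))))[2]
  expect_lt(slope, -0.25)
})

test_that("sequential estimate forgets rasters outside its geometric window", {
  set.seed(207)
  W <- random_rbm(2, 2, 4)
  s <- c(1, 0); a <- c(0, 1)
  p <- runif(4, 0.3, 0.7)
  recent <- bernoulli_raster(p, 400)
  old1 <- bernoulli_raster(rep(0.9, 4), 300)
  old2 <- bernoulli_raster(rep(0.1, 4), 300)
  run_with_prefix <- function(old) {
    est <- ife_sequential(matrix(s, 2, 300), matrix(a, 2, 300), old, W,
                          alpha_h = 0.05, alpha_f = 0.05)
    ife_sequential(matrix(s, 2, 400), matrix(a, 2, 400), recent, W, est = est)$F_hat
  }
  # (1 - 0.05)^400 < 1e-8: the prefix influence is negligible
  expect_equal(run_with_prefix(old1), run_with_prefix(old2), tolerance = 1e-6)
})
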