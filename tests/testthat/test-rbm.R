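test_that("energy matches the naive triple-loop oracle", {
  expect_equal(rbm_energy(1, numeric(0), 1,
                          rbm_weights(matrix(2), matrix(numeric(0), 0, 1))), -2)
  expect_equal(rbm_energy(c(1, 0), c(1), c(0, 0, 0),
                          random_rbm(2, 1, 3)), 0)
  set.seed(101)
  for (i in 1:20) {
    W <- random_rbm(4, 3, 5)
    s <- rbinom(4, 1, 0.5); a <- rbinom(3, 1, 0.5); h <- rbinom(5, 1, 0.5)
    expect_equal(rbm_energy(s, a, h, W), naive_energy(s, a, h, W))
  }
  expect_error(rbm_energy(1, 1, 1, random_rbm(2, 1, 1)), "match")
})

test_that("hidden posterior matches exact enumeration and saturates properly", {
  W0 <- rbm_weights(matrix(0, 2, 3), matrix(0, 1, 3))
  expect_equal(hidden_posterior(c(1, 0), 1, W0), rep(0.5, 3))
  Wsat <- rbm_weights(matrix(20), matrix(0, 1, 1))
  expect_equal(hidden_posterior(1, 0, Wsat)[1], 1, tolerance = 1e-8)
  set.seed(102)
  for (i in 1:10) {
    W <- random_rbm(3, 2, 6)
    s <- rbinom(3, 1, 0.5); a <- rbinom(2, 1, 0.5)
    expect_equal(hidden_posterior(s, a, W), brute_force_posterior(s, a, W),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("free energy equals the brute-force negative log partition", {
  # zero weights: F = -H ln 2
  W0 <- rbm_weights(matrix(0, 2, 7), matrix(0, 1, 7))
  expect_equal(free_energy(c(1, 1), 1, W0), -7 * log(2))
  # one hidden unit, single coupling: F = -ln(1 + e^w)
  w <- 1.3
  W1 <- rbm_weights(matrix(w), matrix(0, 1, 1))
  expect_equal(free_energy(1, 0, W1), -log(1 + exp(w)))
  # random instances vs enumeration
  set.seed(103)
  for (i in 1:40) {
    n_h <- sample(1:10, 1)
    W <- random_rbm(sample(1:4, 1), sample(1:3, 1), n_h)
    s <- rbinom(nrow(W$w_sh), 1, 0.5); a <- rbinom(nrow(W$w_ah), 1, 0.5)
    expect_equal(free_energy(s, a, W), brute_force_free_energy(s, a, W),
                 tolerance = 1e-9)
  }
})

test_that("negative free energy is invariant under hidden permutations", {
  set.seed(104)
  W <- random_rbm(3, 2, 8)
  s <- c(1, 0, 1); a <- c(0, 1)
  perm <- sample(8)
  Wp <- rbm_weights(W$w_sh[, perm], W$w_ah[, perm])
  expect_equal(free_energy(s, a, W), free_energy(s, a, Wp))
})

test_that("softmax action selection has the stated distribution", {
  W <- rbm_weights(matrix(0, 1, 2), matrix(0, 2, 2))
  acts <- list(c(1, 0), c(0, 1))
  set.seed(105)
  picks <- replicate(2000, select_action_rbm(1, W, acts, beta = 1))
  expect_equal(mean(picks == 1), 0.5, tolerance = 0.05)
  # two actions with -F differing by ln 3 at beta = 1 -> probabilities 1:3.
  # Build it with a single action-specific coupling and verify via the
  # closed form first.
  Wd <- rbm_weights(matrix(0, 1, 1), matrix(c(0, log(3)), 2, 1))
  q <- c(-free_energy(1, c(1, 0), Wd), -free_energy(1, c(0, 1), Wd))
  p2 <- exp(q[2]) / sum(exp(q))
  picks2 <- replicate(3000, select_action_rbm(1, Wd, acts, beta = 1))
  expect_equal(mean(picks2 == 2), p2, tolerance = 0.04)
  # beta = Inf is the argmax
  expect_true(all(replicate(20, select_action_rbm(1, Wd, acts, beta = Inf)) == 2))
  expect_error(select_action_rbm(1, W, list(), 1), "at least one")
})

test_that("SARSA update follows the finite-difference gradient of -F", {
  set.seed(106)
  for (i in 1:5) {
    W <- random_rbm(3, 2, 4)
    s <- rbinom(3, 1, 0.5); a <- c(1, 0)
    s2 <- rbinom(3, 1, 0.5); a2 <- c(0, 1)
    tr <- ferl_transition(s, a, r = 2, s_next = s2, a_next = a2)
    gamma <- 0.9; alpha <- 1e-3
    W2 <- sarsa_update(W, tr, gamma, alpha)
    delta <- attr(W2, "delta")
    expect_equal(delta, 2 - gamma * free_energy(s2, a2, W) + free_energy(s, a, W))
    # central finite differences of -F wrt each coupling
    eps <- 1e-6
    for (idx in sample(length(W$w_sh), 4)) {
      Wp <- W; Wm <- W
      Wp$w_sh[idx] <- Wp$w_sh[idx] + eps
      Wm$w_sh[idx] <- Wm$w_sh[idx] - eps
      g <- (-free_energy(s, a, Wp) + free_energy(s, a, Wm)) / (2 * eps)
      expect_equal(W2$w_sh[idx] - W$w_sh[idx], alpha * delta * g,
                   tolerance = 1e-6)
    }
    for (idx in sample(length(W$w_ah), 3)) {
      Wp <- W; Wm <- W
      Wp$w_ah[idx] <- Wp$w_ah[idx] + eps
      Wm$w_ah[idx] <- Wm$w_ah[idx] - eps
      g <- (-free_energy(s, a, Wp) + free_energy(s, a, Wm)) / (2 * eps)
      expect_equal(W2$w_ah[idx] - W$w_ah[idx], alpha * delta * g,
                   tolerance = 1e-6)
    }
  }
})

test_that("a positive TD error lowers the pair's free energy and vice versa", {
  set.seed(107)
  for (i in 1:10) {
    W <- random_rbm(3, 2, 5)
    s <- rbinom(3, 1, 0.5); s[1] <- 1
    a <- c(1, 0)
    # terminal transitions give delta = r + F(s, a); choose r to set the sign
    F0 <- free_energy(s, a, W)
    tr_pos <- ferl_transition(s, a, r = -F0 + 10, terminal = TRUE)
    W_pos <- sarsa_update(W, tr_pos, gamma = 0.99, alpha = 1e-3)
    expect_lt(free_energy(s, a, W_pos), F0)
    tr_neg <- ferl_transition(s, a, r = -F0 - 10, terminal = TRUE)
    W_neg <- sarsa_update(W, tr_neg, gamma = 0.99, alpha = 1e-3)
    expect_gt(free_energy(s, a, W_neg), F0)
  }
})

test_that("zero TD error leaves weights unchanged", {
  W <- random_rbm(2, 2, 3)
  s <- c(1, 0); a <- c(1, 0)
  tr <- ferl_transition(s, a, r = -free_energy(s, a, W), terminal = TRUE)
  W2 <- sarsa_update(W, tr, gamma = 0.99, alpha = 0.1)
  expect_equal(W2$w_sh, W$w_sh)
  expect_equal(W2$w_ah, W$w_ah)
})

test_that("the exact RBM agent solves the center reaching maze", {
  # tabular agent: one-hot states (7) and actions (2), exact free energies.
  # Rewards are expressed in units of 1000 here: at the raw scale the
  # sigmoid posterior saturates (couplings must sum to ~47000), the free
  # energy degenerates into an additive state-plus-action score, and no
  # state-dependent preference can be represented. Policies are invariant
  # to the common reward rescaling.
  set.seed(108)
  W <- rbm_weights(matrix(rnorm(7 * 12, 0, 0.1), 7, 12),
                   matrix(rnorm(2 * 12, 0, 0.1), 2, 12))
  onehot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }
  acts <- list(left = onehot(1, 2), right = onehot(2, 2))
  gamma <- 0.99; alpha <- 0.05; beta <- 0.5
  for (ep in 1:400) {
    pos <- sample(c(0L, 6L), 1)
    s <- onehot(pos + 1, 7)
    ai <- select_action_rbm(s, W, acts, beta = beta)
    for (k in 1:30) {
      mv <- center_step(pos, c(-1L, 1L)[ai])
      r <- mv$reward / 1000
      if (mv$done) {
        W <- sarsa_update(W, ferl_transition(s, acts[[ai]], r,
                                             terminal = TRUE), gamma, alpha)
        break
      }
      pos2 <- mv$pos; s2 <- onehot(pos2 + 1, 7)
      ai2 <- select_action_rbm(s2, W, acts, beta = beta)
      W <- sarsa_update(W, ferl_transition(s, acts[[ai]], r,
                                           s_next = s2, a_next = acts[[ai2]]),
                        gamma, alpha)
      pos <- pos2; s <- s2; ai <- ai2
    }
  }
  # greedy policy reaches the goal in 3 steps from both ends
  for (start in c(0L, 6L)) {
    pos <- start
    for (k in 1:3) {
      ai <- select_action_rbm(onehot(pos + 1, 7), W, acts, beta = Inf)
      mv <- center_step(pos, c(-1L, 1L)[ai])
      pos <- mv$pos
      if (mv$done) break
    }
    expect_equal(pos, 3L)
  }
})

test_that("CD-k reduces reconstruction error on a simple pattern set", {
  set.seed(109)
  v <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  v <- v[rep(1:2, each = 10), ]
  w <- matrix(rnorm(6 * 4, 0, 0.01), 6, 4)
  errs <- numeric(300)
  for (i in 1:300) {
    w <- cd_k(w, v, k = 1, lr = 0.5)
    errs[i] <- attr(w, "recon_error")
  }
  expect_lt(mean(tail(errs, 50)), mean(errs[1:20]))
  expect_lt(mean(tail(errs, 50)), 0.1)
  # lr = 0 leaves weights unchanged
  w2 <- cd_k(w, v, k = 3, lr = 0)
  expect_equal(unclass(w2), unclass(w), ignore_attr = TRUE)
  expect_error(cd_k(w, v[0, , drop = FALSE], 1, 0.1), "empty")
})

test_that("CD-1 matches the hand-computed expected update on a two-visible toy", {
  # 2 visible, 1 hidden, w = 0: positive phase is v * 0.5; the negative
  # phase reconstruction is v' h with h ~ Bern(0.5), v' ~ Bern(0.5) iid, so
  # E[neg] = E[v'_i h] = 0.25. Expected update: lr * (0.5 v - 0.25).
  set.seed(110)
  v <- matrix(c(1, 1), 1, 2)
  lr <- 1
  upd <- replicate(20000, {
    w <- cd_k(matrix(0, 2, 1), v, k = 1, lr = lr)
    as.numeric(w)
  })
  expect_equal(rowMeans(upd), c(0.25, 0.25), tolerance = 0.02)
})
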