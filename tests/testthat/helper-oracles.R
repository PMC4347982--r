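# Independent oracles used across the suite: brute-force enumeration over all
# hidden configurations, naive summation loops, and random model instances.

# random RBM instance with small dimensions
random_rbm <- function(n_s, n_a, n_h, sd = 1) {
  rbm_weights(matrix(rnorm(n_s * n_h, 0, sd), n_s, n_h),
              matrix(rnorm(n_a * n_h, 0, sd), n_a, n_h))
}

# energy by naive triple loop
naive_energy <- function(s, a, h, W) {
  e <- 0
  for (i in seq_along(s)) for (l in seq_along(h))
    e <- e - s[i] * W$w_sh[i, l] * h[l]
  for (j in seq_along(a)) for (l in seq_along(h))
    e <- e - a[j] * W$w_ah[j, l] * h[l]
  e
}

# all binary hidden configurations, one per row
hidden_grid <- function(n_h) {
  as.matrix(expand.grid(rep(list(0:1), n_h)))
}

# free energy as the negative log partition of the clamped chain,
# F = -ln sum_h exp(-E(s,a,h))
brute_force_free_energy <- function(s, a, W) {
  H <- hidden_grid(ncol(W$w_sh))
  -log(sum(exp(-apply(H, 1, function(h) naive_energy(s, a, h, W)))))
}

# exact posterior p(h_l = 1 | s, a) by enumeration
brute_force_posterior <- function(s, a, W) {
  H <- hidden_grid(ncol(W$w_sh))
  w <- exp(-apply(H, 1, function(h) naive_energy(s, a, h, W)))
  colSums(H * w) / sum(w)
}

# iFE by a naive loop over bins and all index pairs
naive_ife <- function(s_spk, a_spk, h_spk, W) {
  N <- ncol(h_spk)
  e <- 0
  for (t in seq_len(N))
    e <- e + naive_energy(s_spk[, t], a_spk[, t], h_spk[, t], W)
  h_bar <- rowMeans(h_spk)
  xlx <- function(x) if (x <= 0) 0 else x * log(x)
  ent <- sum(vapply(h_bar, function(p) xlx(p) + xlx(1 - p), numeric(1)))
  e / N + ent
}

# deterministic Bernoulli rasters for estimator tests
bernoulli_raster <- function(p, N) {
  matrix(rbinom(length(p) * N, 1, rep(p, N)), length(p), N)
}
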