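# snnferl

Spiking neural network realization of free-energy-based reinforcement
learning (FERL).

## The problem

In FERL, the negative equilibrium free energy of a restricted Boltzmann
machine (RBM) serves as the state-action value function: with binary state
nodes **s**, action nodes **a** and hidden nodes **h** coupled through
undirected weights,

    E(s, a, h) = - Σ_il s_i w_sh[il] h_l - Σ_jl a_j w_ah[jl] h_l
    F(s, a)    = E[E | s, a] - H(h | s, a)          (closed form via the
                                                     hidden posterior)
    Q(s, a)    = -F(s, a)

and SARSA temporal-difference learning updates every coupling with a local,
TD-error-modulated Hebbian rule: `Δw = α δ s_i ĥ_l`, with
`δ = r - γ F(s', a') + F(s, a)`.

This package replaces the RBM's binary nodes with leaky integrate-and-fire
neurons (alpha-function synapses, absolute refractoriness, noise currents)
and estimates the free energy from spikes alone — either from window-mean
firing rates (aFE) or from per-bin instantaneous energies (iFE, batch or
fully online/sequential) — so that the whole loop of perception, action
selection (by comparing action-population spike counts) and value learning
runs as a spiking network. Three maze tasks of increasing partial
observability exercise it: a 7-state center-reaching maze, the same maze
observed through digit bitmaps, and a digit-matching T-maze that needs a
working-memory layer (fixed circular-Gaussian ring attractor couplings plus
topographically pretrained observation-to-memory weights).

It is aimed at computational-neuroscience researchers who want a compact,
fully testable reference implementation of spike-based value estimation:
every spike-derived quantity is validated in the test suite against exact
RBM computations or brute-force enumeration.

## Worked example

Train a spiking agent on the center-reaching maze (7 states, goal in the
middle, reward 50000 at the goal, -1000 per move; optimal discounted return
47015 from either end) and compare it with its equivalent RBM:

```r
library(snnferl)

cfg   <- agent_config("center", estimator = "ife_batch")
agent <- build_agent(cfg, seed = 101)
fit   <- train_agent(agent, ferl_env("center"), episodes = 300, seed = 101)

glance(fit)
#>     task estimator episodes median_steps_to_goal goal_rate
#> 1 center ife_batch      300                    6      0.94
#>   median_discounted_return median_reward_sum mean_F
#> 1                    42649             45000 -32268

# equivalent RBM: same couplings divided by c = 1000
eq <- fe_equivalence(fit$agent, c = 1000, shuffle = "independent", seed = 1)
eq$r_fe            # SNN -iFE vs exact RBM -F across the 14 state-action pairs
#> [1] 0.998
eq$r_posterior_shuffled   # collapses toward 0 under weight shuffling
#> [1] 0.01
```

The shortest possible path is 3 actions and the optimal discounted return is
47015: this run's trailing-window medians (6 steps, return 42649 — within
10% of the optimum) reflect a real property of the implementation discussed
in the methods vignette: behavior sits at the 3-step optimum through roughly
the first hundred episodes, after which the lowest-valued (far-from-goal)
state populations fall silent and selection there degrades. The free-energy
equivalence with the scaled RBM (`r_fe` = 0.998 here) is the architecture's
central claim and is insensitive to that. The static spike-count preference
correlation (`action_preference_correlation()`) is *not* reproduced at high
values in this implementation — see the vignette's limitations before using
it.

`autoplot(fit)` draws the learning curves, `plot_weights(fit$agent$W)` the
learned coupling matrices, and `tidy(fit)` returns the per-episode log as a
tibble. A thin command-line front end is available as `exec/snnferl`
(`snnferl train --task center --estimator ife-batch --episodes 200 --seed 1
--out run/`).

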