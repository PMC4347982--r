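---
title: "Spiking free-energy reinforcement learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking free-energy reinforcement learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(snnferl)
```

## The model

`snnferl` implements a spiking realization of free-energy-based
reinforcement learning (FERL). The value function is carried by a restricted
Boltzmann machine (RBM): binary state nodes $s_i$ and action nodes $a_j$ are
coupled to hidden nodes $h_l$ through undirected weights $w^{sh}_{il}$,
$w^{ah}_{jl}$, with energy

$$E(\mathbf{s},\mathbf{a},\mathbf{h}) = -\sum_{i,l} s_i w^{sh}_{il} h_l
  - \sum_{j,l} a_j w^{ah}_{jl} h_l,$$

and the negative equilibrium free energy $-F(\mathbf{s},\mathbf{a})$ — the
expected energy minus the entropy of the exact hidden posterior
$\hat h_l = \sigma(\sum_i w^{sh}_{il} s_i + \sum_j w^{ah}_{jl} a_j)$ — serves
as the state-action value $Q(\mathbf{s},\mathbf{a})$. SARSA
temporal-difference learning moves each coupling along the gradient of
$-F$:

$$\delta_k = r_{k+1} - \gamma F(\mathbf{s}_{k+1},\mathbf{a}_{k+1})
  + F(\mathbf{s}_k,\mathbf{a}_k), \qquad
  \Delta w^{sh}_{il} = \alpha\,\delta_k\, s_i \hat h_l,\quad
  \Delta w^{ah}_{jl} = \alpha\,\delta_k\, a_j \hat h_l.$$

`free_energy()`, `sarsa_update()` and friends implement this exact reference
model; every spike-based quantity in the package is validated against it (or
against brute-force enumeration over all $2^H$ hidden configurations) in the
test suite.

## The spiking network

The RBM's nodes are replaced by leaky integrate-and-fire neurons
(`lif_params()`): $\tau_m = 10$ ms, $V_{rest} = V_{reset} = -70$ mV,
$V_{thres} = -55$ mV, $C_m = 250$ pF (so $R_m = 40\,\mathrm{M\Omega}$),
absolute refractory period 2 ms. Synaptic currents follow an alpha kernel
$\alpha(t) = (t/\tau_{syn})\,e^{1-t/\tau_{syn}}$ with $\tau_{syn} = 2$ ms
(rise time; the kernel peaks at the synaptic amplitude in pA), summed over
presynaptic spike arrivals (see the synaptic-integration note below for the
optional windowed variant). The RBM couplings are
used directly as synaptic amplitudes in pA: state/observation neurons project
to hidden neurons, and hidden and action neurons are bidirectionally coupled
through the same (symmetric) matrix, which TD updates preserve.

Integration uses exponential Euler on the leak at `dt = 0.1` ms — exact for
currents held constant across a step — with spike rasters binned at
$\Delta t = 1$ ms. Since $\Delta t \le t_{ref}$, a bin holds at most one
spike, which the spike-based free-energy estimators require. Refractoriness
is bookkept so a neuron may fire again exactly $t_{ref}$ after its previous
spike; a hard-driven neuron therefore emits exactly 50 spikes per 100 ms at
$t_{ref} = 2$ ms, the theoretical ceiling of the model. Synaptic delays
default to 1 ms everywhere; `randomize_delays` redraws them uniformly in
$[0.5, 5]$ ms per episode (the delay-randomization experiment).

Two dynamical conventions deserve emphasis, because the formal model leaves
them open and the package's behavior hinges on them:

* **Noise correlation time.** The noise current is piecewise constant,
  redrawn i.i.d. $N(0, \sigma^2)$ per neuron every `noise_dt` = 1 ms (the
  convention of standard simulators' noise generators), not per 0.1 ms
  integration step. The noise exists to keep neurons in an irregular-firing
  regime; at 1 ms it produces a subthreshold membrane s.d. of about 5 mV,
  which does that, while per-step white noise (s.d. 1.7 mV) leaves undriven
  neurons permanently silent — network activity then dies wherever couplings
  sag, the Hebbian factor $\bar s_i \bar h_l$ vanishes, and those states can
  never recover (we observed exactly this as frozen "dead zones" at the
  maze's start states).
* **Synaptic integration across spikes.** The windowed synaptic sum can be
  read as erasing a neuron's accumulated kernels at each of its own spikes.
  Standard LIF implementations do not do this — alpha currents integrate
  across postsynaptic spikes — and at the working firing rates (about
  300 Hz) literal clearing erases most synaptic drive and flattens the
  weight-to-rate transfer; with it the maze policy plateaus around 8 steps.
  The default is therefore `clear_on_spike = FALSE`, with the literal
  clearing available as a switch.

## Pseudo-free-energy estimators

Spikes only approximate the binary nodes, so $F$ must be estimated from
activity. Three estimators are provided over the last $N = 100$ bins of the
action phase:

* **aFE** (`afe()`): window-mean firing indicators $\bar s_i, \bar a_j,
  \bar h_l$ substituted everywhere in the closed-form free energy.
* **batch iFE** (`ife_batch()`): the mean over bins of the *instantaneous*
  energy $E(\mathbf{s}(t), \mathbf{a}(t), \mathbf{h}(t))$, plus the entropy
  term of the window-mean hidden rates. Per-bin coincidences between visible
  and hidden spikes survive this average; they are exactly what the aFE
  destroys, and the package reproduces the finding that learning succeeds
  with the iFE but not with the aFE.
* **sequential iFE** (`ife_sequential()`): an online version needing no
  spike storage; running hidden probabilities $\hat h_l \leftarrow \hat h_l +
  \alpha_h (h_l(t) - \hat h_l)$ feed a per-bin sample $\hat f(t) = E(t) +
  \sum_l [h_l \ln \hat h_l + (1 - h_l)\ln(1 - \hat h_l)]$ that is low-pass
  filtered with rate $\alpha_f$. Defaults $\alpha_h = \alpha_f = 0.05$ give
  an effective memory of about 20 bins; the filters are initialized at
  $\hat h_l = 1/2$ and at the first bin's sample. All logarithms clamp their
  arguments to $[10^{-12}, 1 - 10^{-12}]$; entropy terms use the
  $0\ln 0 = 0$ convention.

## Agent, cycle and tasks

One interaction cycle lasts 1000 ms: a 500 ms observation phase (the active
state/observation code receives $I_e$; action neurons are undriven, their
activity coming from hidden feedback plus noise — the minimal reading of
spike-count-based selection) and a 500 ms action phase (state drive stays
on; the selected action block receives $I_e$, the others the suppressive
current). The action is the block with more spikes over the last 100 ms of
the observation phase, ties broken uniformly — the counting window mirrors
the estimator window, a choice the tasks leave open. Rate statistics and the
free-energy estimate come from the last 100 ms of the action phase; the TD
update for step $k$ is applied after step $k+1$'s estimate is available
(terminal transitions are updated immediately, dropping the $\gamma$ term,
and episodes truncated by the cycle cap drop their final transition).

The three tasks:

* **Center reaching** (`ferl_env("center")`): 7 states, goal in the middle
  (state 3), start at either end, reward 50000 at the goal and -1000 per
  other move, with moves off the ends clipped in place at the same penalty
  (the boundary rule is otherwise unspecified). 90 state neurons split into
  7 contiguous blocks (13/13/13/12/13/13/13 — only the total is
  prescribed); injections 1000/-2000 pA, noise 600 pA.
* **Digit center reaching**: the same maze observed through 22×22 digit
  bitmaps, one pixel per observation neuron, pixel intensity scaling the
  injected current; the digit class equals the state index.
* **Digit-matching T-maze** (`ferl_env("tmaze")`): a start node, a
  single-node corridor (configurable length) and a junction; digits 0/1
  shown at start and junction; turning right pays +20000 when they match and
  -500 otherwise, reversed on mismatch; both action blocks act as "forward"
  in the corridor. Injections 2000/-5000 pA, noise 300 pA; 50 memory neurons
  with fixed circular-Gaussian recurrent couplings
  ($g_s = 40$, $g_w = (\pi/72)^2$, $g_b$ from the quadrature formula
  $0.1\,g_s \int_0^{2\pi} e^{(\cos x - 1)/g_w} dx \approx 0.4375$) and
  observation-to-memory couplings pretrained by CD-3 under a circular
  neighborhood-smoothing constraint (`topographic_cd3_pretrain()`,
  $\sigma = \pi/12$) — a deliberate simplification of a full topographic
  RBM objective that preserves its operative property: distinct digit
  classes activate distinct, contiguous positions on the memory ring.

Episodes are capped at 50 cycles (10 in the T-maze). Membrane and synaptic
state are reset at episode boundaries. Exploration relies on intrinsic noise
only; nothing is annealed.

## Parameters that matter, and how the open ones were set

| parameter | default | status |
|---|---|---|
| $\gamma$ | 0.99 | chosen so the optimal discounted return from either end of the center maze is $-1000 - 1000\gamma + 50000\gamma^2 = 47015$, the task's stated optimum; configurable |
| $\alpha$ | 0.001 | not prescribed; see below |
| initial weights | $N(20, 11.88^2)$ | prescribed; keeps neurons in a firing regime |
| $I_e$, noise | task presets | prescribed per task |
| $\tau_{syn}$, delays | 2 ms, 1 ms | NEST-style defaults; unprescribed |
| $\alpha_h, \alpha_f$ | 0.05 | only "smooth tracking" is required; swept in tests |
| $N$, $\Delta t$ | 100 bins, 1 ms | prescribed window; bin must not exceed $t_{ref}$ |

The TD learning rate deserves its own note. The value scale of the center
task is $\sim 5\times 10^4$ and window-mean rate products are $\sim 0.05$,
so the per-update change of $-F$ is roughly $\alpha\,\delta \sum (\bar s
\bar h)^2$. At $\alpha = 10^{-5}$ the value estimate moves by only a few
units per rewarded episode and could not reach the task's value scale within
hundreds of episodes; at $\alpha = 10^{-2}$ episodes destabilize (weights
overshoot, hidden activity collapses, behavior degrades in bursts).
$\alpha = 10^{-3}$ reaches the behavioral optimum within a few hundred
episodes and drives trained couplings to the $O(10^2\text{–}10^3)$ pA range
— consistent with the fact that a well-calibrated equivalent RBM is only
obtained after dividing the trained weights by $c = 1000$. It is the
package default; $5\times 10^{-4}$ is equally stable but slower.

## What the synthetic digits emulate — and what they do not

`synth_digit_bank()` renders stroke-template glyphs (10 variants per class,
22×22 or 20×15, one-pixel affine jitter, 5% pixel flips). Like the reduced
handwritten sets they stand in for, variants of a class are highly
correlated, classes overlap in pixel space (shared strokes), and bitmaps are
essentially binary; held-out variants classify at $\ge 95\%$ by nearest
centroid. They are *easier* than handwritten digits — no style variation,
no slant, no thickness changes — so digit-task results here demonstrate the
architecture's mechanics (high-dimensional drive, topographic memory
activation), not handwriting-level robustness. An IDX reader
(`read_idx()`/`idx_digit_bank()`) accepts real MNIST files unchanged when
genuine difficulty is wanted.

## Numerical choices and degenerate inputs

* Exponential-Euler on the leak is exact for piecewise-constant input, so
  the integration error enters only through threshold-crossing
  discretization (one step, 0.1 ms); the simulated interspike interval is
  held to the closed form $t_{ref} + \tau_m \ln\frac{R_m I + V_{rest} -
  V_{reset}}{R_m I + V_{rest} - V_{thres}}$ within one step in the tests.
* Exact spike-count ties in action selection are broken uniformly at
  random; degenerate equivalence analyses (constant free energies, e.g.
  zero weights) return `NA` correlations with an explicit flag rather than
  an error.
* The firing-pattern distance (analysis of recurring patterns) is the
  normalized Hamming distance between binned population vectors —
  equivalent to squared Euclidean distance on 0/1 vectors; the metric was
  left open and Euclidean-on-rates is available as an option. Dominant
  periodicity is the lag in 2..20 bins minimizing the mean distance.
* The memory ring at its stated parameters has a very narrow excitatory
  peak (width $\pi/72$ against a neuron spacing of $2\pi/50$), so the
  recurrent drive alone (peak ~40 pA against a 375 pA rheobase) cannot
  sustain activity after input offset in this integration scheme. The
  couplings are built exactly as stated; `memory_trace()` exposes a
  `recurrent_gain` factor, and the persistence and history-readout tests
  document the gain at which self-sustained bumps appear. This is recorded
  as a known limitation rather than silently rescaled inside the agent.

## Problem sizes used by the tests and the acceptance script

Simulation studies in the suite are sized for a desk-scale reproduction:
the learning study runs two seeds per estimator at the full 300-episode
budget and summarizes the trailing 50 episodes; the equivalence analyses
probe one trained agent with a handful of repetitions per state; the
acceptance script trains a single 300-episode agent from the seed it is
given. These sizes are stated in the tests and the script themselves. Two
seeds resolve the estimator contrast's median gap deterministically but are
underpowered for a rank test over such bimodal episode distributions; the
corresponding assertion is kept at the study's stated form and its outcome
discussed under limitations.

## Known limitations

* **Far-state silencing.** The network encodes state value in the product of
  coupling strength and firing rate, so far-from-goal states — whose values
  are lowest — are driven toward the firing threshold as learning raises the
  value scale. Training therefore shows the maze's 3-step optimum early
  (roughly the first hundred episodes) and then degrades to a median of
  about 6 steps as the outermost state blocks fall silent and action
  selection there becomes a coin flip. The discounted return stays within
  10% of the optimum, and the iFE-vs-aFE contrast is unaffected, but the
  trailing-window median of steps does not hold the $\le 4$ level over a
  300-episode run. No learning-rate setting we probed ($2\times 10^{-4}$ to
  $10^{-2}$) removes the effect; slower rates only trade it against capped
  episodes.
* **Online correction, not static preference.** Spike-count action selection
  succeeds during training largely through within-episode TD correction: a
  wrong choice's negative surprise immediately weakens that action's
  couplings until the alternative wins. Frozen-weight evaluation is
  noticeably worse than the training curve, and static probes of the
  left/right count difference show an activity profile plus a global bias
  rather than a per-state preference flip. Consequently the count-vs-iFE
  preference correlation across states measures only about 0.2–0.5 here,
  far below the equivalence between the network's values and its RBM
  counterpart (0.99 under $c = 1000$ scaling), which does reproduce.
* The aFE agent's failure to learn is reproduced as a *relative* deficit
  (rank test against iFE over seeds); individual aFE seeds occasionally
  luck into short episodes.
* T-maze learning is demonstrated mechanically (cycles run, memory carries
  digit identity across the corridor) but not trained to optimum in the
  test suite; its budget would be out of scale with the rest of the suite.
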