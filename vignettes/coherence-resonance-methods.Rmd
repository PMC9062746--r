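---
title: "Methods: coherence resonance in two-layered excitatory-inhibitory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherence resonance in two-layered excitatory-inhibitory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhnlayers)
```

## The model

`fhnlayers` simulates a population of $N$ FitzHugh-Nagumo neurons in the
excitable regime, split into an excitatory layer (neurons $1..N_E$) and an
inhibitory layer ($N_E+1..N$), with $N_I = \mathrm{round}(N\gamma_I)$.
Each neuron obeys

$$\dot V_i = c\,(V_i - V_i^3/3 - w_i) + D\,\eta_i
          + K_{\cdot E} V^E_i - K_{\cdot I} V^I_i, \qquad
  \dot w_i = (V_i - b\,w_i + a)/c,$$

with $a = 0.8$, $b = 0.9$, $c = 4.5$. $V^E_i$ and $V^I_i$ are diffusive
sums $\sum_j M_{ji}(V_j - V_i)$ over presynaptic excitatory and inhibitory
neighbours respectively; the coupling coefficient depends on the
postsynaptic type ($K_{EE}, K_{IE}$ for excitatory, $K_{EI}, K_{II}$ for
inhibitory targets; all default to 0.2). Excitatory input always enters
with a plus, inhibitory input with a minus sign. At these constants the
noise-free neuron has a single stable rest state
$(V^*, w^*) \approx (-1.307, -0.563)$ (computed by `fhn_fixed_point()` via
bracketed root-finding and an eigenvalue stability check), and
supra-threshold perturbations trigger one large excursion — a spike.

## Network construction

*Intralayer.* Neurons are placed uniformly at random in the unit square
and two same-layer neurons are linked bidirectionally iff their Euclidean
distance is strictly below $R_{th}$ (a random geometric graph, no periodic
boundary). The default $R_{th} = 0.126$ is calibrated so that at
$\gamma_I = 0.1$ the ensemble-mean intralayer degree of the excitatory
(majority) layer is $k = 8.0$. We verified this convention numerically:
with the same radius the pooled two-layer mean is $\approx 7.3$, while the
excitatory-layer mean is $8.0$, so the reference calibration is defined on
the majority layer; `degree_statistics()` reports both. The inverse
calibration `calibrate_rth()` bisects the radius against a fixed ensemble
of position draws (common random numbers), which makes the ensemble-mean
degree exactly monotone in $R_{th}$ and the root well-defined despite the
stochastic objective.

*Interlayer.* Every neuron gets a fitness $f_i = (i/N)^{1/(1-\beta)}$
($\beta = 2.5$), shuffled uniformly across both layers. An
excitatory-inhibitory pair is a candidate link iff
$\Theta < f_i f_j / L_{ij}^\delta$ with $L_{ij}$ the planar distance.
Rather than adjusting $\Theta$ iteratively, `calibrate_theta()` sorts all
$N_E N_I$ pair scores and places $\Theta$ between the order statistics
bracketing the target link count $\mathrm{round}(N \bar k_I / 2)$
(default $\bar k_I = 2.0$), so every generated network hits the target
*exactly*; score ties at the cut are broken by pair index. Each qualifying
pair carries exactly one directed link: E$\to$I with probability $\xi$,
I$\to$E otherwise. Small $\delta$ yields heterogeneous, scale-free-like
interlayer degrees (variance/mean $\approx 20$ at $\delta = 0.5$,
$\gamma_I = 0.3$); large $\delta$ restricts links to nearby pairs and
gives near-Poisson degrees (variance/mean $\approx 1.4$ at $\delta = 10$).

The standard parameter set is $N = 200$, $\gamma_I = 0.2$, $\xi = 0.5$,
$\beta = 2.5$, $\bar k_I = 2.0$, all $K = 0.2$. No standard value of
$\delta$ is singled out by the dynamics (we verified the resonance
optimum is insensitive to $\delta$ over $[0.5, 10]$); the package default
is $\delta = 0.5$, the heterogeneous regime, which is also the
configuration that sustains the most regular activity.

## Integration and the noise convention

The integrator (`integrate_network()`, compiled) advances the drift with
the two-stage Heun (trapezoidal) rule at a fixed step $dt = 0.01$ and adds
the noise increment $D\,\eta\,dt$, $\eta \sim N(0,1)$ redrawn per neuron
and step, to the fast variable only. Two numerical points deserve
emphasis:

- *Accuracy.* In the noise-free limit the scheme is second order: on the
  single-neuron spike excursion it tracks an adaptive high-accuracy ODE
  solution within $10^{-3}$ sup-norm at $dt = 0.01$ (a first-order Euler
  step leaves a $\approx 0.05$ phase error on the fast downstroke), and
  halving the step shrinks the error about fourfold.
- *Noise convention.* The noise term treats $\eta$ as a unit-variance
  Gaussian force held constant over one step, so the increment is
  $D\,\eta\,dt$ and the effective white-noise intensity is $D\sqrt{dt}$ at
  the reference step. All $D$ values quoted by the package refer to this
  convention; under it the coherence-resonance optimum falls at
  $D \approx 10\!-\!15$. (Under the alternative It\^o reading
  $D\sqrt{dt}\,\eta$ the same dynamics saturate by $D \approx 1$ and
  diverge near $D \approx 20$, so the two conventions are easy to tell
  apart empirically.)

All neurons start at rest $(V^*, w^*)$ and the first `t_transient = 100`
time units are discarded, which removes initialization sensitivity. The
noise stream is a dedicated xoshiro256++/Box-Muller generator seeded by an
integer, so trajectories are bitwise reproducible and independent of R's
RNG state. Divergence (non-finite or runaway state) aborts with the step
index; `run_realization()` redraws such realizations with a recorded
replacement seed (none occur at the default step).

## Coherence measures

Regularity is quantified per neuron by the normalized autocorrelation of
the membrane potential over the post-transient window,

$$C_i(\tau) = \frac{\langle \tilde V_i(t)\,\tilde V_i(t+\tau)\rangle}
                   {\langle V_i^2\rangle - \langle V_i\rangle^2},
  \qquad \tilde V_i = V_i - \langle V_i\rangle,$$

and the characteristic correlation time
$T_i = \int_0^{\tau_{\max}} C_i^2(\tau)\, d\tau$ (trapezoidal quadrature).
Averages $\bar T$, $\bar T_E$, $\bar T_I$ are arithmetic means over the
population and the layers; the identity
$N_E \bar T_E + N_I \bar T_I = N \bar T$ holds exactly. Choices worth
stating:

- Angle brackets are *time* averages over a single realization (ergodic
  reading); realization-to-realization variability is handled by averaging
  $\bar T$ over independent (network, noise) draws.
- The estimator is the *biased* one (normalizing by the full window at
  every lag), computed via FFT: it keeps $|C| \le 1$, is positive
  semidefinite, and matches direct summation to $10^{-8}$.
- The correlation-time integral is truncated at
  $\tau_{\max} = 200$ time units (configurable; it must not exceed half
  the analysed window). The autocorrelation of noisy spiking at these
  parameters decays within tens of time units, and the resonance-curve
  shape is stable to doubling $\tau_{\max}$.
- Traces with variance below $10^{-12}$ (e.g. $D = 0$ at rest) get
  $T_i = 0$ — "no oscillation, no coherence" — keeping the weak-noise limit
  of resonance curves well-defined.

The estimators are validated on synthetic signals with known structure
(`generate_ou()`, `generate_sine()`, `generate_white()`,
`generate_pulse_train()`): an exactly discretized Ornstein-Uhlenbeck
process with relaxation time $\tau_c$ has $T = \tau_c/2$ analytically and
is recovered within 10% for records of $2000\,\tau_c$ (the squared-ACF
noise floor adds a positive bias that only long records suppress); a
sinusoid gives
$C(\tau) = \cos\omega\tau$; jittered pulse trains confirm that the metric
ranks signals by regularity (periodic > low jitter > high jitter > white
noise). The pulse bump is a raised cosine; the shape is irrelevant to the
ordering. These fixtures exercise the estimator, not the neural model:
they have no excitability, no refractoriness, and no network interactions,
so passing them validates the measurement pipeline, not the simulated
biology.

## Sweeps and reproducibility

`run_realization()` derives a network seed and a noise seed from one
realization seed; a fresh network is drawn for every realization, so
ensemble averages include wiring variability as well as dynamical noise.
`run_sweep()` iterates over the Cartesian grid with seeds
`derive_seed(base_seed, grid_index, realization)` — a counter-based scheme
under which grids can be extended without perturbing existing cells and
any single cell can be recomputed in isolation. Paired comparisons (e.g.
$\delta = 0.5$ vs $\delta = 10$) reuse the same realization seeds on both
sides to cancel seed-level variability.

The reference protocol averages 50 realizations per grid point; the
shipped analyses and tests use 10 realizations of 500 post-transient time
units each, which keeps every sweep within minutes on one core while
leaving the qualitative pattern unambiguous: $\bar T(D)$ is non-monotonic
with an interior optimum near $D = 10\!-\!15$; coherence increases with
$\gamma_I$ and with $K_{IE}$, and decreases with $\xi$ and with $\delta$.
Standard errors at a grid point follow the $1/\sqrt{n}$ law, so the
reference protocol tightens these estimates without moving them.

## Degenerate inputs and limitations

Single-layer networks ($\gamma_I \in \{0, 1\}$) are permitted with a
warning; the empty layer's average is reported as `NA`, never zero.
Isolated neurons are left as-is (no connectivity repair). Coincident
placements (zero interlayer distance) have probability zero and are
guarded by redrawing positions. The model deliberately omits chemical
synapses, delays, autapses, plasticity, and any fitness-dynamics
correlation; the noise convention ties quoted $D$ values to the reference
step $dt = 0.01$ (comparisons across different steps must rescale by
$\sqrt{dt}$ to keep the effective intensity fixed).

```{r example, eval = FALSE}
# one realization at the resonance optimum
net <- build_network(network_params(seed = 1))
traj <- integrate_network(net, dynamics_params(D = 10, seed = 2))
coh <- compute_coherence(traj)
coh

# desk-scale resonance curve
sp <- sweep_spec(list(D = c(1, 5, 10, 15, 20, 40)), n_realizations = 10)
res <- run_sweep(sp)
find_resonance_peak(res, "D")
```
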