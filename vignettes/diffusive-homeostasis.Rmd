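---
title: "Diffusive homeostasis in spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusive homeostasis in spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Nitric oxide (NO) is a membrane-permeant gas that neurons synthesize in an
activity-dependent way and that regulates intrinsic excitability. Because it
diffuses freely through tissue, a neuron's NO level reports a mixture of its
own activity and that of its neighbours. This package implements a spiking
network model of homeostatic intrinsic plasticity (HIP) driven by such a
*diffusive* signal, alongside the canonical *non-diffusive* (cell-autonomous)
variant, and quantifies what the difference does to firing-rate
heterogeneity and network responsiveness.

# The model

## Network

`run_network()` integrates a recurrent network of `N` conductance-based
leaky integrate-and-fire neurons (80% excitatory, 20% inhibitory) with
fixed-step forward Euler at `dt = 0.1` ms:

$$\frac{dv}{dt} = \frac{E_l - v}{\tau_m}
  + \frac{g_e (E_e - v) + g_i (E_i - v) + g_{ext} (E_e - v)}{c_m}
  + \sigma_{OU}\,\eta(t),$$

where the synaptic gating variables decay exponentially
($\tau_e = 3$ ms, $\tau_i = 7$ ms) and jump by the synaptic conductance
($J_e = 5.5$ nS, $J_i = g J_e = 64$ nS) on each presynaptic spike. A spike
is fired when $v$ crosses the threshold $\theta_i$ (initially $-50$ mV),
after which $v$ is clamped at $v_r = -60$ mV for $\tau_{ref} = 5$ ms.
Connectivity is sparse and random: every ordered pair is connected
independently with probability $C/N$ ($C = 100$), irrespective of neuron
type and of spatial position; a Gaussian distance-dependent profile on the
unit torus (`build_connectivity(spatial_s =)`) is available as a variant.
These parameters put the network in an inhibition-dominated balanced state
producing asynchronous irregular spiking (ISI coefficient of variation
near 1).

Three readings of the printed model equations deserve note, since they are
ambiguous as published and the choices are visible in the code:

* **Capacitance.** Synaptic currents in nS·mV are divided by
  $c_m = 0.2$ nF so the units of the membrane equation close. With
  $\tau_m = 20$ ms this corresponds to a 10 nS leak conductance; the
  parameter set is essentially the classic conductance-based balanced
  network benchmark, which is known to produce asynchronous irregular
  activity under this reading.
* **External input.** Each neuron receives an independent Poisson train at
  its own rate $\mu_i$, realized as per-step Bernoulli events
  ($p = \mu_i\,dt \le 3\times10^{-3}$ at the rates used). Arrivals
  increment a dedicated exponential conductance with amplitude
  $J_{ext} = 80$ nS and decay $\tau_e$. $J_{ext}$ is large: a single
  external arrival from rest normally triggers a spike, so before
  homeostasis acts the network roughly relays its external drive, and
  thresholds then set the relay gain. We adopted this conductance reading
  because the alternative (a small instantaneous voltage kick) leaves the
  calibration network silent, which is inconsistent with a procedure that
  defines the homeostatic target from its activity.
* **Noise.** $\eta(t)$ is a unit-variance Ornstein–Uhlenbeck process
  ($\tau_{OU} = 1$ ms) updated with its exact discrete solution;
  $\sigma_{OU}\eta$ enters $dv/dt$ directly with $\sigma_{OU}$ read in
  mV/ms, giving ~1 mV of stationary membrane noise.

Synaptic transmission has no delays; increments take effect at the
integration step after the presynaptic spike. Autapses are excluded.

## NO synthesis, diffusion, and threshold control

Each spike adds a fixed quantum to an intracellular calcium variable that
decays with $\tau_{Ca} = 10$ ms. Calcium activates nNOS through a Hill
function (exponent 3, half-activation 1); active nNOS relaxes toward that
Hill level with $\tau_{nNOS} = 100$ ms. As printed, the nNOS synthesis
equation has no decay term and would grow without bound; the first-order
relaxation used here is the bounded reading consistent with the NO field
reaching a steady state, and it preserves the stated time constant.

NO spreads on a periodic $1\,\mathrm{mm}^2$ sheet by an explicit
forward-time centred-space (FTCS) step of

$$\frac{\partial [NO]}{\partial t} = D \nabla^2 [NO] - \lambda [NO]
 + \sum_i [nNOS]_i\,\delta(x - x_i),$$

with $D = 1000\ \mu m^2/s$, $\lambda = 0.1\,/s$, grid spacing
$ds = 2\ \mu m$ (default; coarser grids are used at reduced scale) and a
1 ms chemistry timestep. Stability requires $D\,dt/ds^2 \le 0.25$ and is
checked at construction. Neurons are point sources at their (random,
connectivity-independent) positions and read the concentration of their
own grid cell. The non-diffusive variant integrates the same equation
without the Laplacian, per neuron. Concentration units are arbitrary: only
the ratio to the target enters the control law.

Thresholds follow the relative-error rule
$d\theta_i/dt = \left([NO]_i - [NO]_0\right) / \left(\tau_{HIP} [NO]_i\right)$
with $\tau_{HIP} = 2500$ ms, applied at the 1 ms chemistry step (the
homeostatic timescale makes the coarser cadence indistinguishable from
updating every 0.1 ms). Neurons whose NO signal is not yet positive are
skipped and counted (`guard_skips`), which only happens during startup
transients. $\theta$ is unbounded. The combined mode sums a diffusive and
a non-diffusive relative-error term, each with its own timescale and its
own independently calibrated target.

The target $[NO]_0$ is *calibrated*, not chosen: the network runs for
100 s without homeostasis under uniform input and the target is the mean
NO concentration across neurons at the end (`calibrate_no_target()`). The
variable-target control (`draw_variable_targets()`) instead samples
per-neuron targets, with replacement, from the steady-state intracellular
NO distribution of a homeostasis-free network driven by a broad Gaussian
input-rate distribution; targets are resampled rather than matched
one-to-one because group membership and position are independent anyway.

## Inputs (the synthetic-data stage)

All experiment inputs are generated internally by `draw_static_rates()`
(i.i.d. Gaussian rates, negatives clipped to zero — a Poisson process
cannot have a negative rate; the pre-clip draw is kept because input
*changes* are analysed on the underlying Gaussian), `assign_groups()`,
`time_varying_pattern()` (independent Gaussian group offsets, sd 25 Hz,
regenerated every second) and `orientation_rates()` (Gaussian tuning,
base 20 Hz, peak 2.5 Hz, width 90°, full 360° period with circular
distance). They emulate stationary or piecewise-stationary Poisson drive
with prescribed first and second moments; they do not emulate temporally
correlated or naturalistic stimuli, nor spatially structured input maps.

## STDP

`run_network(stdp = TRUE)` adds additive spike-timing-dependent plasticity
to every recurrent E→E synapse: for a pre/post pair separated by
$\Delta t = t_{pre} - t_{post}$, the weight changes by
$A_+ e^{\Delta t/\tau_+} g_{max}$ for $\Delta t < 0$ and by
$-A_- e^{-\Delta t/\tau_-} g_{max}$ otherwise
($A_+ = 0.025 < A_- = 0.0275$, $\tau_\pm = 20$ ms), hard-clipped to
$[0, g_{max} = 10\ \mathrm{nS}]$. Pairing is nearest-neighbour in the
symmetric per-spike form: each presynaptic spike pairs with the partner's
most recent postsynaptic spike and vice versa (the exact bookkeeping
variant is not specified in the source material; the symmetric form is the
standard one for this rule). Weight updates apply immediately;
transmission uses the current weight. Initial weights are
$\mathcal{N}(7.5, 2.5^2)$ nS clipped to the bounds. `shuffle_weights()`
permutes final weights across existing connections for the shuffled-weight
control, preserving the degree structure and the weight histogram.

## Dynamic mean field

The mean-field module reduces diffusive signalling to a single mixing
parameter $\alpha$: each neuron in a non-interacting population updates
its threshold from a weighted mix of its own rate error
(weight $1-\alpha$) and the population's (weight $\alpha$). Rates come
from the Ricciardi first-passage formula for the LIF neuron
(`lif_transfer_rate()`, reduced units $\theta_0 = 10$, $v_r = 0$,
$\tau_m = 20$ ms),

$$\phi(\mu, \sigma, \theta) = \left[\sqrt{\pi}\,\tau_m
 \int_{(v_r-\mu)/\sigma}^{(\theta-\mu)/\sigma} e^{u^2}\,
 \mathrm{erfc}(-u)\,du\right]^{-1},$$

evaluated with the scaled complementary error function (stable for large
$|u|$) and fixed-order Gauss–Legendre quadrature vectorized over the
population. Two reconstructions were necessary here. The source prints the
prefactor as $\pi$ and renders the input statistics as
$\mu_i = \sigma_i = JC\nu\tau$; both are typographically corrupted. We use
the standard diffusion-approximation forms — prefactor $\sqrt{\pi}$ and
$\sigma_i = J\sqrt{C\nu\tau}$ — which are the only readings under which
the formula agrees with a direct stochastic simulation of the same neuron
(`lif_sim_rate()`, checked to within 3% across a $(\mu,\sigma)$ grid in
the test suite). $\sigma$ follows the convention in which the stationary
free-membrane sd is $\sigma/\sqrt 2$. No refractory term is included, as
printed. External inputs enter as per-neuron offsets
$\mu_i \sim \mathcal{N}(5.7, \delta^2)$ with $\sigma_i = \sqrt{\mu_i}$.

`solve_self_consistent()` iterates the population rate to $10^{-4}$ Hz
(damped fixed point; with $J = 0$, the population used throughout the
experiments, one evaluation is exact). `mf_homeostasis()` takes Euler
steps of the $\alpha$-mixed threshold rule, recomputing all rates after
each step; relative errors are clamped below at $-50$ so that a neuron
whose rate collapses toward zero takes a large but finite corrective step.
`build_covariance_population()` imitates homeostasis outcomes directly by
drawing $(\mu_i, \theta_i)$ from a Gaussian copula with prescribed
correlation.

# Reduced-scale protocol

Full-scale runs ($N = 5000$, $500 \times 500$ grid, hundreds to thousands
of simulated seconds) reproduce the model as published but take hours of
CPU. The test suite and the acceptance script instead run the complete
protocols at the desk scale returned by `desk_protocol()`: $N = 1000$
neurons, a $48 \times 48$ grid, and one to three simulated minutes per
phase (calibration 20 s, homeostasis 70 s, probes 15–20 s each). Four scalings make the small model behave like the large
one rather than like a distorted version of it; all four are fixed
properties of the protocol, chosen on the mechanistic grounds below.

* **Time compression (k = 5).** The slow processes are sped up fivefold
  ($\tau_{HIP} = 500$ ms, $\lambda = 0.5\,/s$) and all protocol durations
  divided by five. Membrane, synaptic and Ca/nNOS constants are untouched,
  so the spiking regime is identical; only the separation between
  homeostasis and rate fluctuations shrinks.
* **Diffusive-range scaling.** Holding the diffusive range
  $\ell = \sqrt{D/\lambda} = 100\ \mu m$ fixed while shrinking $N$
  5-fold would leave only ~30 neurons within range of each neuron (vs
  ~160 at full scale), with two finite-size consequences: a neuron's own
  point source contributes a much larger share of the NO it samples
  (making "diffusive" homeostasis behave cell-autonomously), and the
  sampled field is spatially rougher, injecting threshold scatter that is
  absent at full scale. Because the relay-like transfer of this network
  makes per-neuron gain steep in $\theta$, that scatter is enough to mask
  the conditions' differences. The desk protocol therefore enlarges
  $\ell$ to 450 µm, restoring both the full-scale ratio of
  local-differentiation time to protocol duration and the smoothness of
  the sampled field. The diffusive signal then sits close to the global
  limit — appropriate for a reduced model whose job is to preserve the
  full-scale contrast between conditions.
* **Calibration drive.** At full scale the calibrated target rate sits at
  about half the mean probe input (5 Hz calibration against
  $\mathcal{N}(10, 10^2)$ Hz probes). The small network has a higher
  background gain (about 3× at low rates), so calibrating at 5 Hz would
  put the target *above* the mean input and park every condition in the
  saturated relay regime where thresholds hardly matter. The desk
  protocol calibrates at 1.5 Hz, which reproduces the full-scale
  target-to-input ratio (target ≈ 5 Hz vs mean input 10 Hz).
* **Variable-target calibration.** The broad input distribution for the
  variable-target control is, by construction, tuned so that the
  resulting rate distribution matches the diffusive network's; at desk
  scale that tuning gives $\mathcal{N}(0.8, 2.5^2)$ Hz (full scale:
  $\mathcal{N}(2, 5^2)$ Hz).

What the desk-scale runs do and do not show: the qualitative contrasts —
broad vs collapsed rate distributions, long vs short persistence of input
differences, more vs less linear responses, better vs worse tracking and
decoding — are asserted in `tests/testthat/test-acceptance.R` and
recomputed by `scripts/acceptance.R`. Absolute values (a persistence time
in seconds, an $R^2$) are scale-dependent and are reported, not asserted.
STDP protocols use a 600–800 neuron network with $C = 150$–250 and
$J_{ext} = 40$ nS, 250–400 s of plasticity.

# Numerical choices and degenerate inputs

* Forward Euler at 0.1 ms: halving `dt` changes a 10 s single-neuron
  spike count by well under 1% (asserted in the tests); conductance and
  OU decays use exact exponential factors.
* The simulation core consumes one seed per run segment and uses its own
  xoshiro256++ generator, so every run is bit-reproducible from
  `(state, seed)` independently of the caller's R RNG state; R-level
  generators (`draw_static_rates()` etc.) use R's RNG and `set.seed()`.
* FTCS stability ($D\,dt/ds^2 \le 0.25$) is validated at configuration
  time; `scaled_config()` caps $D$ at the bound for the chosen grid.
* Zero or negative calibration drive, empty groups, constant series in
  the tracking metric, zero population vectors in the decoder, and
  non-positive NO in the threshold rule are all rejected or skipped with
  explicit errors/counters rather than propagating NaNs; the integrator
  aborts with a diagnostic if the membrane state becomes non-finite.
* In `lif_transfer_rate()` the quadrature bounds grow like
  $(\theta - \mu)/\sigma$; configurations whose integrand overflows
  (essentially silent neurons at tiny $\sigma$) raise an error instead of
  returning 0, which in the homeostasis loops is prevented by the
  error-clamp on relative rate errors.

A note on the decoding experiment: the population vector is computed from
*stimulus-evoked* responses — each neuron's trial rate minus its own
across-trial baseline, rectified at zero. Decoding raw rates instead adds
each network's quenched rate-heterogeneity as a fixed bias vector; at
$N = 5000$ this bias is negligible, but at desk scale it dominates the
decoder and randomizes condition comparisons. Trials last 5 s so that
per-trial Poisson noise does not mask the structural differences.

# Known limitations

* At desk scale the combined-timescales sweep shows the correct monotone
  broadening of the rate distribution as the non-diffusive mechanism
  slows, but the dynamic range of the trend is compressed relative to the
  full-scale figure: with fivefold-compressed homeostasis both mechanisms
  come close to their joint fixed point within the run, at which the slow
  mechanism still pins per-neuron rates substantially.
* In the mean-field linearity sweep the package reproduces the high, flat
  $R^2$ at narrow input widths and the overall drop at wide ones, but not
  the decline at high $\alpha$ for $\delta = 1$: without a refractory
  term the transfer function does not saturate from above, which removes
  the mechanism that penalizes a common threshold at very wide input
  ranges.
* Per-neuron response gains retain quenched scatter from the random
  connectivity (binomial in-degree variation, notably the ~22% relative
  spread of inhibitory in-degree at $C = 100$); this sets the $R^2$
  ceiling at any scale and is a property of the model, not of the
  implementation.
* In the orientation task, diffusive homeostasis decodes more precisely
  than non-diffusive homeostasis at desk scale, but the additional deficit
  of the variable-target control (clear at full scale) is smaller than the
  network-to-network spread at $n = 1000$ and is therefore reported, not
  asserted.
* The spatial concentration maps of the full-scale model (structured NO
  landscapes over a 500×500 grid) are only meaningful at fine grid
  resolution; desk-scale grids are too coarse for map-level comparisons.
* Boundary conditions other than periodic are out of scope.
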