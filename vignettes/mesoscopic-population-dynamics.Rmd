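---
title: "Mesoscopic population dynamics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscopic population dynamics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesopop)
```

## The scientific problem

Cortical circuits are naturally described as a small number of
interacting populations of similar neurons — the excitatory and
inhibitory cells of each lamina, say — with 50 to a few tens of
thousands of neurons per population. At these sizes the population
activity $A_N(t)$ (the fraction of neurons spiking per unit time,
binned at $\Delta t$) is visibly stochastic: finite-size fluctuations
do not average out, and because single neurons are refractory and
adapting, those fluctuations are strongly history-dependent — a burst
of activity silences the population for the next few milliseconds.
Classical rate models (Wilson–Cowan-type equations) ignore both the
fluctuations and their interplay with refractoriness.

`mesopop` implements two levels of description of the same network and
the machinery to show they agree:

* **Microscopic** (`run_micro()`): every neuron is a generalized
  integrate-and-fire (GIF) unit with escape noise. The membrane
  potential integrates synaptic input with time constant $\tau_m$, is
  reset to $u_r$ after a spike and clamped there for an absolute
  refractory period $t_{ref}$; every spike also adds a kernel
  $\theta(t) = \sum_\ell (J_\ell/\tau_\ell) e^{-t/\tau_\ell}$ to the
  neuron's firing threshold, producing adaptation (positive $J$),
  facilitation (negative $J$) and, via $\theta = \infty$ on
  $(0, t_{ref})$, absolute refractoriness. Spikes are emitted
  stochastically with hazard $\lambda = c\,
  e^{(u - \vartheta)/\Delta_u}$. A spike-response/GLM variant replaces
  the reset by a spike-after-potential kernel $\eta$.
* **Mesoscopic** (`run_meso()`): one stochastic update per population
  per time step. The state is the refractory density — how many
  neurons fired their last spike in each of the past $K$ bins —
  summarized by the *expected* survival numbers $\bar m_k$ and their
  variances $v_k$, plus a "free" pool for neurons whose last spike is
  older than the explicit history $T = K \Delta t$. Each step computes
  the expected spike count
  $$\bar{\Delta n} = \sum_k P_\lambda(t|t_k)\,\bar m_k
    + P_{free}\,x + P_\Lambda \Big(N - \sum_k \bar m_k - x\Big),$$
  and samples the actual count $\Delta n \sim B(N, \bar{\Delta n}/N)$.
  The last term is the finite-size correction: because the simulator
  tracks only expected survivals, the pseudo-density is not normalized,
  and the deficit ("holes and overshoots" left behind by past
  fluctuations) fires with the effective probability
  $$P_\Lambda = \frac{\sum_k P_\lambda v_k + P_{free} z}
    {\sum_k v_k + z},$$
  the variance-weighted average of the per-state firing
  probabilities. The variances follow their own closed recursion,
  $v_k \leftarrow (1-P_\lambda)^2 v_k + P_\lambda \bar m_k$, so the
  whole construction is driven by the realized activity history alone.

Two approximations connect the levels: the mean-field replacement of
random connectivity (fixed in-degree $pN$) by full connectivity with
weights scaled to $J = pNw$, and the quasi-renewal treatment of
adaptation, in which threshold contributions of spikes *before* the
last one are averaged over the population history with the kernel
$\tilde\theta(t) = \Delta_u[1 - e^{-\theta(t)/\Delta_u}]$. Both become
exact for fully connected, non-adapting populations.

The intermediate binomial survival-number process
(`run_density_micro()`) simulates the refractory distribution itself
with integer counts and binomial decrements; it conserves the neuron
number exactly and is the bridge used to validate the moment closure.

## Parameters that matter

| parameter | unit | default | meaning |
|---|---|---|---|
| `tau_m` | s | 0.02 | membrane time constant (relative refractory time scale) |
| `t_ref` | s | 0.004 | absolute refractory period; also the upper bound on `dt` |
| `u_th`, `u_r`, `u_rest` | mV | 15, 0, 0 | baseline threshold, reset, rest |
| `c` | 1/s | 10 | escape rate at threshold |
| `delta_u` | mV | 2 | threshold softness; rate grows $e$-fold per `delta_u` of depolarization |
| `theta` | mV·s, s | empty | spike-triggered kernel components $(J_\ell, \tau_\ell)$ |
| `tau_s` | s | 0.003/0.006 | synaptic decay, excitatory/inhibitory sources |
| `delay` | s | 0.001 | transmission delay; lower bound on information flow between populations |

The explicit-history length `T` is chosen per population by
`choose_history_length()`: at least $5\max(t_{ref}, \tau_m)$ (so the
relative refractory period has decayed) and long enough that
$|\theta(t)| \le 0.01\,\Delta_u$ beyond it, after which the kernel
tail is absorbed into the free-neuron threshold through exponential
auxiliary variables $g_\ell$. A slow kernel therefore does *not* force
a long history as long as its amplitude density $J/\tau$ is small. The
0.01 tolerance is a package choice, exposed as `tol_theta` in
`sim_settings()`.

## Numerical scheme

Time is discretized in steps `dt` that must not exceed any $t_{ref}$
(at most one spike per neuron per step) nor any delay (populations
decouple within a step); `validate_dt()` enforces both and probes a
third, trajectory-dependent condition — the accuracy of the
trapezoidal hazard average $\bar\lambda = [\lambda(t_l) +
\lambda(t_{l+1})]/2$ — on a short deterministic run, because it
depends on the realized solution and cannot be checked a priori.

Membrane potentials and synaptic filters are advanced with the exact
one-step solution of the coupled linear system under piecewise-constant
drive (delayed activities and stimuli are constant over a bin); the
degenerate case $\tau_s = \tau_m$ uses the $t e^{-t/\tau}$ limit
formula. The microscopic simulator uses the same exact update per
neuron, with the delayed afferent spike count of a bin treated as a
constant rate over the step; at full connectivity the micro and meso
drive formulas are then literally identical, which is what makes
machine-precision cross-checks possible. Per-step threshold evaluation
is $O(K)$ thanks to the running-sum sweep of the quasi-renewal
contributions; the brute-force $O(K^2)$ summation is retained in the
pure-R reference implementation (`run_meso_reference(brute_force =
TRUE)`) and agrees to machine precision.

Numerical safeguards: the hazard exponent is clamped at $+20$ before
exponentiation (the per-step firing probability saturates at 1 anyway);
$\bar{\Delta n}$ is clipped to $[0, N]$ before sampling; binomial
sampling (rather than Poisson) is the default because it respects the
hard bound $\Delta n \le N$ when a large fraction of the population
fires in one step; Poisson (truncated) and Gaussian sampling are
available as the theory's stated variants, and `sampling = "expected"`
gives the deterministic infinite-$N$ proxy. Refractory-state buffers
are circular, indexed modulo $K$. Cohorts whose hazard is still zero
(inside $t_{ref}$) contribute $P_\lambda = 0$ exactly; the cohort
whose dead time ends within the current step receives half a step of
hazard from the trapezoid — the discrete analog of the jump in the
hazard — and the closed-form special case below honors the same
convention.

## Initial conditions

Three initializations are provided. `"synchronized"` (all neurons
fire at $t = -\Delta t$) is the classic sharp initial condition and is
convenient for analysis, but in strongly coupled networks it is
dynamically treacherous: whole cohorts exit the refractory period
together, and if the recurrent excitation arriving at that moment is
strong enough the population locks into a self-sustaining cluster
state firing at $1/t_{ref}$, which finite-size noise cannot break at
large $N$. This is a genuine attractor of the synchronized dynamics,
not a numerical artifact — the microscopic simulator shows it too —
but it is not the spontaneous state one wants to measure.
`"free"` starts all neurons without spike history at rest.
`"stationary"` (mesoscopic runs only) starts in the asynchronous
stationary state computed by `stationary_rates()`, a damped
fixed-point iteration of the integrator's own discretized stationary
map (survival profile under the mean recurrent input, quasi-renewal
threshold under constant activity, free pool fixed by normalization).
For the cortical-column model the fixed point reproduces the fitted
target rates to about 1% and the stochastic dynamics stays in its
neighborhood, so spontaneous-activity statistics can be measured
without long transients.

## Design choices where the design was open

* **Autapses.** Fixed in-degree wiring samples presynaptic partners
  without replacement and excludes the neuron itself — except at full
  connectivity within a population, where the in-degree contract
  ($pN$ synapses) requires the self-connection. This keeps the
  realized microscopic coupling equal to the mesoscopic $J = pNw$;
  strongly coupled small networks are sensitive to even a $1/N$
  mismatch there.
* **Non-integer quantities.** In-degrees $pN$ and delays
  $\Delta/\Delta t$ are rounded (with a message); $t_{ref}$ is mapped
  to $\max(1, \mathrm{round}(t_{ref}/\Delta t))$ steps.
* **Degenerate effective probability.** When all variances vanish
  (e.g. right after synchronization) the normalization deficit is zero
  and $P_\Lambda$ is formally undefined; the free-neuron probability
  is used, the choice consistent with the $N \to \infty$ limit.
* **GLM variant.** The after-potential enters the refractory states as
  $u_k = h + \eta(t - t_k)$, i.e. only the last spike's
  after-potential is tracked explicitly; longer-lived contributions
  should be folded into the threshold kernel (the hazard is invariant
  under $\theta \to \theta - \eta$, $\eta \to 0$).
* **Winner-take-all wiring.** The bistable preset gives each
  excitatory population self-excitation and a projection to the common
  inhibitory population, which inhibits both excitatory populations
  and itself; the two excitatory populations are not directly coupled,
  so competition is purely inhibitory. The architecture is symmetric
  under exchange of the excitatory populations.
* **Column weights.** In the eight-population column all excitatory
  weights are 0.176 mV and all inhibitory ones −0.702 mV, with the
  single documented exception of the doubled L4e→L2/3e projection
  (0.351 mV). With these conventions the fitted resting potentials,
  the target rates and the package's deterministic stationary map are
  mutually consistent to better than 0.1 mV for every population.

## What the validation shows — and what it does not

The test suite validates the theory against independent oracles:
the exact closed equation for absolute-refractory Poisson populations
(machine precision, including self-coupling), analytic renewal theory
for uncoupled populations (rates, ISI distributions, power spectra),
closed-form survival/variance laws for constant hazard, dense ODE
solutions for the synaptic integration, and the microscopic simulator
itself for coupled E-I networks (overlapping Monte-Carlo bands of the
spectra), bistable switching statistics and the cortical column. The
synthetic fixtures (`fixture_generator()`) provide Poisson, telegraph
and square-wave traces with known statistics for the analysis tools.

Problem sizes used in the validation runs are deliberately moderate:
populations of 50–2000 neurons for cross-level comparisons, a few
hundred seconds of stationary data for spectra (segment length 1 s or
0.5 s), 150–250 s for switching statistics at $\Delta t = 1$ ms, and
24–30 s averaging windows for the 77,000-neuron column at
$\Delta t = 0.5$ ms.

Passing these tests shows that the mesoscopic closure reproduces the
statistics of *this* microscopic model class. It does not show that
real cortical data follow the model: conductance-based synapses,
voltage-dependent adaptation currents, short-term plasticity,
structured (non-random) connectivity and heterogeneous parameters
within a population are all outside the scope of the generator and the
theory as implemented. Known limitations within scope: the
quasi-renewal approximation degrades for fast, strong threshold
kernels (bursty regimes are captured qualitatively, with some excess
low-frequency power), and the mean-field input approximation requires
$pN$ to be reasonably large — for small, sparsely connected networks
with strong synapses the mesoscopic description deviates from the
microscopic one.

## A worked example

```{r example, eval = FALSE}
pre <- preset_uncoupled_lif(mu = 30, N = 500)
st <- sim_settings(dt = 2e-4, duration = 20, seed = 1,
                   init = "stationary", warmup = 1)
tr <- run_meso(pre$spec, st)
mean(tr$activity)                    # ~36.4 1/s
renewal_stats(pre$spec$populations[[1]], 30)  # rate 36.44, CV 0.157

sp <- power_spectrum(tr, segment_length = 1)
th <- renewal_spectrum(pre$spec$populations[[1]], 30, sp$frequencies)
# sp$power fluctuates around th$power; both approach rate/N at high f
```
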