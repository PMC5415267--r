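# mesopop

Stochastic mesoscopic population dynamics of spiking neural networks.

## What this package is for

Models of cortical circuits often work at the level of interacting
*populations* — the excitatory and inhibitory cells of each cortical
layer, say — each containing only 50 to a few tens of thousands of
neurons. At these sizes the population activity

```
A_N(t) = (number of spikes in [t, t + dt)) / (N dt)
```

fluctuates strongly, and because single neurons are refractory and
adapting, the fluctuations feed back on themselves: a chance burst of
spikes leaves the population silent for the next few milliseconds.
`mesopop` provides a simulator for this regime at two levels:

* **`run_micro()`** — the microscopic reference: a network of
  generalized integrate-and-fire (GIF) neurons with escape noise
  (hazard `lambda = c * exp((u - theta)/delta_u)`), voltage reset,
  absolute refractory period, spike-triggered threshold kernels
  (adaptation/facilitation) and fixed in-degree random connectivity.
* **`run_meso()`** — the package's core: a stochastic *mesoscopic*
  integrator that draws one binomial spike count per population per
  time step from the expected count

  ```
  dn_bar = sum_k P_lambda(t|t_k) m_k  +  P_free x  +  P_Lambda (N - sum_k m_k - x)
  ```

  where `m_k` are expected survival numbers of the neurons whose last
  spike fell in past bin `t_k`, `x` is the free pool, and `P_Lambda`
  — a variance-weighted average firing probability — prices the
  normalization deficit left behind by past finite-size fluctuations.
  Adaptation enters through the quasi-renewal kernel
  `theta_tilde = delta_u (1 - exp(-theta/delta_u))`. The cost per step
  is independent of the number of neurons, so a 77,000-neuron,
  eight-population cortical column integrates in seconds.
* **`run_density_micro()`** — the intermediate binomial
  survival-number process used to validate the closure; it conserves
  the neuron count exactly.

Analysis tools cover the statistics used to compare the levels:
segment-averaged population power spectra (`power_spectrum()`), the
analytic renewal spectrum `C(f) = (r/N)(1-|P_ISI|^2)/|1-P_ISI|^2`
(`renewal_spectrum()`), ISI statistics, trial-averaged PSTHs and
dominance-time statistics of bistable networks (`dominance_times()`).
Turn-key presets reproduce standard benchmark networks: uncoupled LIF
populations, adapting/bursty populations, fully or randomly connected
E-I networks, a winner-take-all bistable circuit, and the modified
eight-population cortical-column model with thalamic step input.

## A worked example

```r
library(mesopop)

pre <- preset_uncoupled_lif(mu = 30, N = 500)   # uncoupled LIF population
st  <- sim_settings(dt = 2e-4, duration = 20, seed = 1,
                    init = "stationary", warmup = 1)
tr  <- run_meso(pre$spec, st)

mean(tr$activity)
#> [1] 36.57
renewal_stats(pre$spec$populations[[1]], 30)
#> <renewal_stats> rate = 36.44 1/s, CV = 0.1575
```

The mesoscopic run of 500 uncoupled neurons fires at 36.6 spikes/s per
neuron, matching the renewal-theory rate for these parameters; the CV
of 0.16 reflects the strong relative refractoriness at this drive.
The fluctuation statistics agree too:

```r
sp <- power_spectrum(tr, segment_length = 1)
th <- renewal_spectrum(pre$spec$populations[[1]], 30, sp$frequencies)
```

`sp$power` scatters around the analytic curve `th$power`, with the
characteristic low-frequency dip of refractory spike trains and the
Poisson plateau `rate/N` at high frequencies.

The same machinery runs the cortical column:

```r
pre <- preset_cortical_column(with_adaptation = FALSE)
st  <- sim_settings(dt = 5e-4, duration = 24, seed = 1, init = "stationary")
tr  <- run_meso(pre$spec, st)
round(colMeans(tr$activity[-(1:4000), ]), 3)
#> L2/3e L2/3i   L4e   L4i   L5e   L5i   L6e   L6i
#> 0.968 2.861 4.679 5.667 8.172 9.058 0.993 7.547
```

matching the model's fitted spontaneous rates (0.974, 2.861, 4.673,
5.65, 8.141, 9.013, 0.988, 7.53 spikes/s) within about 1%.

A thin command-line front end lives at `inst/cli/mesopop.R`
(`preset`, `run`, `spectrum`, `psth`, `dominance` subcommands over
YAML configurations and tab-separated trace files).

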