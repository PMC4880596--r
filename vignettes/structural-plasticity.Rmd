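---
title: "Homeostatic structural plasticity: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic structural plasticity: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mspnet)
```

# The model

`mspnet` simulates networks of leaky integrate-and-fire (LIF) neurons whose
connectivity is not prescribed but *grows*. Each neuron tracks its own mean
activity through an intracellular calcium trace and uses it to decide whether
to offer new synaptic contact points or to withdraw existing ones; a global
connectivity manager turns the offered contact points into synapses. Given
per-population activity setpoints, the network wires itself until every
population fires at its target rate.

The model has three layers, updated on two timescales.

## 1. Electrical activity and calcium (fast, per `dt`)

Membrane potentials follow the standard LIF equation with delta (voltage
jump) synapses: between events, `v` relaxes exponentially toward the resting
potential `e_l`; each presynaptic spike adds its synapse's post-synaptic
amplitude (mV, negative for inhibitory synapses) instantaneously after the
synaptic delay; crossing `v_th` emits a spike, resets `v` and starts an
absolute refractory period. Every neuron additionally receives an
independent Poisson stream of excitatory jumps (the external drive).

Each neuron's calcium trace obeys

    dCa/dt = -Ca/tau          between spikes
    Ca  <-  Ca + beta         at each spike,

so under stationary firing at rate `r` the trace fluctuates around
`beta * r * tau`. With the defaults `beta = 0.001` and `tau = 10000` ms, a
calcium level of 0.05 corresponds to 5 Hz and 0.2 to 20 Hz: calcium is a
linear firing-rate proxy, not a biophysical calcium model. Decay is applied
lazily in closed form (`Ca * exp(-dt/tau)`) at spikes and interval
boundaries, which is exact for this linear equation, so the electrical
integrator's step size never affects the trace.

## 2. Synaptic elements (slow, per structural interval)

Each neuron carries, per element type (axonal `Axon_*`, dendritic `Den_*`),
a continuous variable `z` — its current stock of synaptic contact points.
`z` is integrated under a calcium-dependent growth curve `dz/dt(Ca)`:

* **linear**: `nu * (1 - Ca/eps)` — positive below the setpoint `eps`,
  negative above;
* **gaussian**: `nu * (2 exp(-((Ca - xi)/zeta)^2) - 1)` with
  `xi = (eta + eps)/2`, `zeta = (eps - eta)/(2 sqrt(ln 2))` — zero at `eta`
  (the minimal activity needed to form elements at all) and at `eps`, peak
  rate `nu` midway, and `-nu` far outside `[eta, eps]`.

The squared exponent is required for the Gaussian curve to actually have its
two advertised zero crossings together with the `sqrt(ln 2)` scale; with a
linear exponent those properties are mutually inconsistent, so the squared
form is implemented.

An element exists when `floor(max(z, 0))` crosses an integer; newly formed
elements are *vacant*. `z` may go negative, modelling a deficit that must be
regrown before any element reappears — this damps churn at the zero
boundary. The linear curve is integrated exactly over the structural
interval under pure calcium decay (spikes within the interval are absorbed
into the next interval's starting value); the Gaussian curve takes one
forward-Euler step per interval using the calcium at the interval start.

## 3. Connectivity update (slow, per structural interval)

At the end of every structural interval the manager:

1. collects, per neuron and element type, the number of vacant elements and
   the number of elements whose deletion forces synapse breaking
   (`connected > floor(max(z, 0))`);
2. breaks synapses for deleted elements, sampling the victims uniformly
   without replacement among the neuron's synapses of that type. The
   partner's counterpart element survives and becomes vacant — this is the
   rewiring mechanism — but may only re-match from the *next* interval on;
3. forms new synapses per synapse rule by expanding vacancy counts into one
   sequence per side, shuffling both independently and pairing positionally.
   The probability of two neurons connecting therefore depends only on how
   many compatible vacant elements each offers. Self-pairings are skipped
   (both elements stay vacant) unless autapses are enabled; repeated pairs
   create parallel synapses (multapses), which follows directly from
   element-count-proportional pairing. No topological or distance constraint
   enters the pairing.

An invariant ties the layers together: for every element type, the summed
`connected` counts equal the number of matching edge endpoints in the global
synapse store. The test suite asserts this after every structural interval
of long runs.

# Timescale separation

Connectivity is intended to change about 100 times more slowly than the
electrical state. The engine warns (but does not stop) when
`structural_interval / dt < 100`. The defaults — `dt = 0.1` ms, structural
updates every 10 ms, growth rates of order `1e-4` elements/ms — keep any
single connectivity update small.

# Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `tau` (calcium) | 10000 | ms | rate-averaging window of the calcium trace |
| `beta` | 0.001 | Ca | calcium intake per spike |
| `eps` | per population | Ca | activity setpoint (`eps*100` Hz at defaults) |
| `eta` | 0 | Ca | minimal calcium for element formation (gaussian) |
| `nu` | 1e-4 | elements/ms | peak element growth/retraction speed |
| `tau_m`, `v_th`, `v_reset`, `e_l`, `t_ref` | 10, -55, -70, -70, 2 | ms/mV | LIF parameters (common basic defaults) |
| drive `rate`, `amplitude` | 10000 Hz, 0.122 mV | | external Poisson drive per neuron |
| synapse amplitudes | +1.0 / -g mV | mV | delta-synapse jumps; `g` configurable |
| `delay` | 1.0 | ms | uniform synaptic delay (must be >= `dt`) |
| `structural_interval` | 10 | ms | connectivity-update cadence |
| `prune_fraction` | 0 | per update | fraction of vacant elements removed |

Notes on the less obvious choices:

* **Drive amplitude (0.122 mV).** Because the Gaussian rule with `eta = 0`
  has a root at `Ca = 0`, a completely silent network is a fixed point:
  nothing can ever grow. Self-organization therefore needs spontaneous
  activity. The default amplitude is calibrated so that *disconnected*
  neurons fire at about 1 Hz — well below the lowest setpoint used in the
  bundled models — which seeds element growth without pre-empting the
  homeostatic equilibrium. A nominal amplitude small enough to keep
  disconnected neurons silent (e.g. 0.01 mV at the same rate) stalls the
  network forever.
* **`prune_fraction = 0`.** Pruning removes `fraction * vacant` from `z`
  every interval. Any fraction larger than the per-interval growth
  (`nu * structural_interval`, about 0.001–0.01 in all bundled
  configurations) destroys each fresh vacancy faster than growth can
  ratchet `z` across the next integer, so no synapse can ever form. The
  mechanism is implemented and configurable for studies of vacancy decay,
  but it is off by default.
* **Inhibitory weight `g`.** Only the excitatory amplitude (1.0 mV) is
  fixed by the bundled model descriptions; the inhibitory amplitude is a
  free factor `-g`. The two-population builder defaults to the symmetric
  `g = 1`; the stable desk-scale study conditions use `g = 0.5` (below).

# The two bundled models

`build_two_population(scale, nu_scale, g, ...)` creates the 1000-neuron
(at `scale = 1`) two-population network: 80% excitatory neurons with
Gaussian curves `eta = 0, eps = 0.05` on all three element types
(`Axon_ex`, `Den_ex`, `Den_in`), 20% inhibitory neurons with `eps = 0.2`
and a 4-fold faster `nu` on their excitatory dendrites — the more active
inhibitory population must offer more excitatory contact points early, or
the excitatory population reaches its own equilibrium first and stops
producing axons. Two plastic rules connect the element types:
`Axon_ex -> Den_ex` (+1 mV) and `Axon_in -> Den_in` (`-g` mV). The network
starts with zero synapses.

`build_microcircuit(scale, connectivity_init, ...)` creates the
eight-population, four-layer cortical-microcircuit layout. Population sizes
follow the published counts of the microcircuit model the layout is based
on; the per-population growth parameters ship as clearly labelled
*illustrative defaults* (`inst/extdata/microcircuit_params.yaml`) because
the original growth-curve table is not publicly available: excitatory
setpoints sit below inhibitory ones in every layer, layer 2/3 lowest.
`connectivity_init` supports `"empty"` (fully disconnected),
`"reference"` (pre-connect by sampling a user-supplied 8x8
connection-probability table; element stocks are initialised to exactly the
bound counts) and `"perturbed"` (the same after jittering every table entry
by a relative error, 10% by default). The reference table itself is not
bundled — it is external data the user must supply.

# Desk-scale study conditions

The full-size runs (1000 neurons over 3000 s; ~80000 neurons over 700 s)
are cluster-scale. The package's own experiments — used by its acceptance
tests — are scaled-down surrogates chosen once and kept fixed:

* **Two-population**: `scale = 0.1` (100 neurons), growth rates x5,
  `g = 0.5`, drive 10^4 Hz x 0.122 mV, 400 biological seconds, `dt = 0.1`
  ms, structural updates every 100 steps. Convergence of both populations
  to their setpoints (within a few percent, averaged over the final 20% of
  the run) occurs at around 200 s. At desk scale the symmetric `g = 1`
  either ignites synchronization runaways (each neuron pair carries many
  parallel 1 mV synapses, so avalanches propagate) or locks the network
  into a long inhibition-dominated transient; halving the inhibitory
  amplitude removes both failure modes while preserving the model's
  qualitative trajectory — early excitatory outgrowth, overshoot,
  inhibition-driven rewiring, joint convergence.
* **Microcircuit**: `scale = 0.02` (~1500 neurons), growth rates x5,
  illustrative setpoints, a few hundred biological seconds; all eight
  populations settle near their configured setpoints.

What these scaled runs demonstrate is the *self-organization mechanism* —
homeostatic growth steering a network from (near) emptiness to its activity
targets. They do not reproduce quantitative connectivity statistics of any
full-scale cortical model: at 100–1500 neurons the multapse counts,
correlation structure and finite-size fluctuations differ qualitatively
from the full-size networks, which is also why the desk-scale conditions
needed their own stability working point.

# Numerical choices and degenerate inputs

* Events exactly on an interval boundary belong to the closing interval
  (half-open intervals `[t, t + dt)`); a spike registered at step `s` is
  timestamped `(s+1)*dt`.
* Synaptic delays are stored as integer step counts (`>= 1`); the delivery
  ring buffer dimensions follow the largest rule delay.
* Poisson drive is sampled per neuron per step by inversion from a cached
  CDF table, using R's RNG: a run is bitwise reproducible given
  `set.seed()`/the `seed` argument, including its structural randomness.
* Refractory neurons discard synaptic input (clamped at `v_reset`).
* If a neuron must delete more element instances than it has synapses left
  (because an earlier deletion in the same interval already broke a shared
  synapse), the request is capped — both deletions are honoured without a
  double-free. A report exceeding the connected count is an error.
* `t_total = 0` is a no-op; time is cumulative across successive
  `run_simulation()` calls, which is how stabilize-then-enable protocols
  (`enable_plasticity()` / `disable_plasticity()`) are expressed.
* With plasticity disabled, calcium continues to be tracked so that
  re-enabling later behaves as if plasticity had been paused, not reset.

# Known limitations

* Delta synapses only; no conductance-based or shaped PSCs, and no synaptic
  weight plasticity on formed edges.
* Homogeneous neuron parameters within a population.
* No topology: pairing is global and distance-blind by construction.
* Single-process execution; the global vacancy exchange is an in-memory
  aggregation with the same information content as a distributed
  implementation would communicate.
* The calcium trace is a firing-rate proxy; no biophysical calcium
  buffering or channel dynamics.
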