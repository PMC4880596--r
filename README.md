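# mspnet — self-organizing spiking networks via homeostatic structural plasticity

For most neural circuits, activity (firing rates) is far easier to measure
than connectivity. `mspnet` implements a simulation framework in which a
spiking network *generates its own connectivity* from activity targets:
instead of prescribing who connects to whom, the modeller prescribes how
active each population should be, and the network grows, deletes and
rewires synapses until those targets are met. It is aimed at computational
neuroscientists studying circuit development, rewiring after lesions, and
the automatic generation of connectivity for network models where
connection data are incomplete.

## The model

Three ingredients, two timescales:

1. **Electrical layer (per 0.1 ms).** Leaky integrate-and-fire neurons with
   delta synapses (instantaneous voltage jumps) and an independent Poisson
   background drive per neuron.
2. **Calcium as a rate proxy.** Each neuron integrates
   `dCa/dt = -Ca/τ`, `Ca ← Ca + β` at each spike, so `Ca` fluctuates
   around `β·r·τ` at firing rate `r`. With `β = 0.001`, `τ = 10⁴ ms`,
   `Ca = 0.05` ⇔ 5 Hz.
3. **Structural layer (per 10 ms).** Each neuron grows or retracts
   *synaptic elements* — axonal boutons (`Axon_*`) and dendritic spines
   (`Den_*`) — as a continuous stock `z` per element type, integrated under
   a homeostatic growth curve, either linear

       dz/dt = ν (1 − Ca/ε)

   or Gaussian

       dz/dt = ν (2·exp(−((Ca − ξ)/ζ)²) − 1),   ξ = (η+ε)/2,  ζ = (ε−η)/(2√ln2),

   which is zero at the minimum activity `η` and at the setpoint `ε`, and
   peaks at `ν` (elements/ms) midway. An element exists when `⌊max(z,0)⌋`
   crosses an integer; new elements are *vacant*. At every structural
   interval a global connectivity manager breaks the synapses of deleted
   elements (the partner element survives and becomes vacant — rewiring)
   and pairs compatible vacant elements uniformly at random into new
   synapses, so connection probability depends only on how many compatible
   vacant elements two neurons offer. Multapses arise naturally; autapses
   are skipped by default.

Two network builders ship with the package: a two-population (80%
excitatory / 20% inhibitory) self-organizing network, and an
eight-population, four-layer cortical-microcircuit layout driven by a
parameter file of documented illustrative defaults, with optional
pre-connected (`reference` / `perturbed`) initial conditions sampled from a
user-supplied connection-probability table. See the vignette
(`vignettes/structural-plasticity.Rmd`) for the full model description and
the reasoning behind every default.

## Worked example

Build the desk-scale two-population network (100 neurons, growth rates ×5,
inhibitory weight −0.5 mV) and let it wire itself for 60 biological
seconds:

```r
library(mspnet)
net <- build_two_population(scale = 0.1, nu_scale = 5, g = 0.5)
run <- run_simulation(net, t_total = 60000, seed = 1)
print(run)
#> Structural-plasticity run up to t = 60 s; 1030 synapses
#> Final mean calcium: excitatory=0.0600, inhibitory=0.0664
connectivity_matrix(run$network)
#>            excitatory inhibitory
#> excitatory        684        204
#> inhibitory        127         15
```

Starting from zero synapses, 60 s of growth has produced 1030 edges
(synapse counts by source/target population above) and pushed the
excitatory population's mean calcium to 0.060 — just past its setpoint of
0.05 (the early excitatory overshoot), while the inhibitory population
(setpoint 0.2, i.e. 20 Hz) is still recruiting excitatory input at 0.066.
Continuing the same run to ~200 s lets inhibition catch up and both
populations settle at their setpoints; `calcium_summary()` reports
per-population convergence times, and `percent_connectivity()` /
`average_error()` compare generated connectivity against a reference map.

## Command-line interface

Thin wrappers over the package functions live in `inst/cli/`:

```sh
Rscript inst/cli/run.R --config model.yaml --seed 1 --t-total 100000 --out out/
Rscript inst/cli/analyze.R compare --a out/percent.csv --b reference.csv
```
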