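# Illustrative default parameters for the eight-population cortical
# microcircuit layout (4 layers x excitatory/inhibitory).
#
# Population sizes follow the published counts of the cortical-microcircuit
# model this layout is based on. The growth-curve setpoints (eps) are
# ILLUSTRATIVE DEFAULTS, not values from any published study: they respect
# the qualitative ordering described for this kind of model (excitatory
# setpoint below the inhibitory one in every layer, layer 2/3 the lowest)
# and, with the default calcium constants (tau = 10000 ms, beta = 0.001),
# translate to target rates of eps * 100 Hz. All curves are Gaussian with
# eta = 0: any positive activity promotes element formation, and elements
# are deleted above the setpoint.
#
# Growth rates: 1.0e-4 elements/ms everywhere except the excitatory
# dendritic elements (Den_ex) of inhibitory populations, which grow 2x
# faster -- mirroring the ratio of inhibitory to excitatory setpoints --
# so the more active inhibitory populations attract enough excitatory
# input to reach their higher setpoints.
#
# The drive amplitude is calibrated so that disconnected neurons fire
# spontaneously at about 1 Hz (the bootstrap condition; see the vignette).

calcium: {tau: 10000.0, beta: 0.001}
neuron: {tau_m: 10.0, v_th: -55.0, v_reset: -70.0, e_l: -70.0, t_ref: 2.0}
drive: {rate: 10000.0, amplitude: 0.122}
prune_fraction: 0.0
allow_autapses: false

synapses:
  synapse_ex:
    pre_synaptic_element: Axon_ex
    post_synaptic_element: Den_ex
    amplitude: 1.0
    delay: 1.0
  synapse_in:
    pre_synaptic_element: Axon_in
    post_synaptic_element: Den_in
    amplitude: -0.5
    delay: 1.0

populations:
  L23e:
    size: 20683
    elements:
      Axon_ex: {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.03, continuous: false}
      Den_ex:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.03, continuous: false}
      Den_in:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.03, continuous: false}
  L23i:
    size: 5834
    elements:
      Axon_in: {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.08, continuous: false}
      Den_ex:  {growth_curve: gaussian, growth_rate: 2.0e-4, eta: 0.0, eps: 0.08, continuous: false}
      Den_in:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.08, continuous: false}
  L4e:
    size: 21915
    elements:
      Axon_ex: {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.045, continuous: false}
      Den_ex:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.045, continuous: false}
      Den_in:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.045, continuous: false}
  L4i:
    size: 5479
    elements:
      Axon_in: {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.09, continuous: false}
      Den_ex:  {growth_curve: gaussian, growth_rate: 2.0e-4, eta: 0.0, eps: 0.09, continuous: false}
      Den_in:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.09, continuous: false}
  L5e:
    size: 4850
    elements:
      Axon_ex: {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.055, continuous: false}
      Den_ex:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.055, continuous: false}
      Den_in:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.055, continuous: false}
  L5i:
    size: 1065
    elements:
      Axon_in: {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.1, continuous: false}
      Den_ex:  {growth_curve: gaussian, growth_rate: 2.0e-4, eta: 0.0, eps: 0.1, continuous: false}
      Den_in:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.1, continuous: false}
  L6e:
    size: 14395
    elements:
      Axon_ex: {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.04, continuous: false}
      Den_ex:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.04, continuous: false}
      Den_in:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.04, continuous: false}
  L6i:
    size: 2948
    elements:
      Axon_in: {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.085, continuous: false}
      Den_ex:  {growth_curve: gaussian, growth_rate: 2.0e-4, eta: 0.0, eps: 0.085, continuous: false}
      Den_in:  {growth_curve: gaussian, growth_rate: 1.0e-4, eta: 0.0, eps: 0.085, continuous: false}
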