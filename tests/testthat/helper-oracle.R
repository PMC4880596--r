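# Independent pure-R reference implementation of the electrical layer,
# kept deliberately simple (explicit per-step loops) so it can serve as an
# oracle for the compiled kernel when both are fed identical event streams.
#
# Semantics: per step s (0-based), each neuron receives the sum of all
# events scheduled for s; refractory neurons sit at v_reset and discard
# input; otherwise v <- e_l + (v - e_l) * exp(-dt/tau_m) + input, and a
# threshold crossing emits a spike at time (s+1)*dt, resets v and starts
# the refractory counter. Calcium decays in closed form between spikes and
# gains beta at each spike.
lif_oracle <- function(n_steps, dt = 0.1, n = 1, params = lif_params(),
                       cal = calcium_params(),
                       events = NULL, edges = NULL) {
  v <- rep(params$e_l, n)
  refrac <- integer(n)
  ca <- numeric(n)
  last_sp <- numeric(n)
  decay <- exp(-dt / params$tau_m)
  ref_steps <- as.integer(round(params$t_ref / dt))
  spikes_t <- numeric(0); spikes_i <- integer(0)
  # pending[[s]] accumulates recurrent deliveries for future steps
  pending <- vector("list", n_steps + 1L)
  vtrace <- matrix(NA_real_, n_steps, n)
  for (s in 0:(n_steps - 1L)) {
    inp <- numeric(n)
    if (!is.null(events)) {
      ev <- events[events$step == s, , drop = FALSE]
      if (nrow(ev)) for (k in seq_len(nrow(ev)))
        inp[ev$neuron[k]] <- inp[ev$neuron[k]] + ev$amplitude[k]
    }
    pd <- pending[[s + 1L]]
    if (!is.null(pd)) for (k in seq_len(nrow(pd)))
      inp[pd$neuron[k]] <- inp[pd$neuron[k]] + pd$amplitude[k]
    for (i in seq_len(n)) {
      if (refrac[i] > 0L) {
        refrac[i] <- refrac[i] - 1L
        v[i] <- params$v_reset
        next
      }
      v[i] <- params$e_l + (v[i] - params$e_l) * decay + inp[i]
      if (v[i] >= params$v_th) {
        v[i] <- params$v_reset
        refrac[i] <- ref_steps
        t_sp <- (s + 1) * dt
        ca[i] <- ca[i] * exp(-(t_sp - last_sp[i]) / cal$tau) + cal$beta
        last_sp[i] <- t_sp
        spikes_t <- c(spikes_t, t_sp); spikes_i <- c(spikes_i, i)
        if (!is.null(edges)) {
          out <- edges[edges$pre == i, , drop = FALSE]
          for (k in seq_len(nrow(out))) {
            tgt_s <- s + out$delay_steps[k]
            if (tgt_s < n_steps) {
              pending[[tgt_s + 1L]] <- rbind(
                pending[[tgt_s + 1L]],
                data.frame(neuron = out$post[k], amplitude = out$amplitude[k]))
            }
          }
        }
      }
    }
    vtrace[s + 1L, ] <- v
  }
  t_end <- n_steps * dt
  ca <- ca * exp(-(t_end - last_sp) / cal$tau)
  list(v = v, ca = ca, vtrace = vtrace,
       spikes = data.frame(time_ms = spikes_t, neuron = spikes_i))
}

# Tiny scripted two-neuron network useful for plasticity bookkeeping tests:
# one excitatory "source" population and one "target", each with explicit
# element counts injected by hand.
make_micro_net <- function(n_a = 2, n_b = 2, allow_autapses = FALSE,
                           prune_fraction = 0) {
  gc <- growth_curve("gaussian", nu = 1e-4, eps = 0.05, eta = 0)
  pops <- list(
    population_spec("A", n_a, elements = list(Axon_ex = gc, Den_ex = gc),
                    drive = external_drive(0, 0)),
    population_spec("B", n_b, elements = list(Axon_ex = gc, Den_ex = gc),
                    drive = external_drive(0, 0)))
  rules <- list(synapse_rule("syn_ex", "Axon_ex", "Den_ex", amplitude = 1))
  sp_network(pops, rules, prune_fraction = prune_fraction,
             allow_autapses = allow_autapses)
}

# Set the z variable of (neuron, type) directly (scripted scenarios).
set_z <- function(net, neuron, type, z) {
  row <- net$elem_idx[match(type, net$types), neuron]
  net$elem$z[row] <- z
  net
}
get_elem <- function(net, neuron, type) {
  row <- net$elem_idx[match(type, net$types), neuron]
  list(z = net$elem$z[row], connected = net$elem$connected[row])
}
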