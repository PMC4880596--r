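#' Leaky integrate-and-fire neuron parameters
#'
#' The electrical layer uses current-free LIF neurons with delta (voltage
#' jump) synapses: between events the membrane relaxes exponentially toward
#' the resting potential, each incoming spike adds its post-synaptic
#' amplitude instantaneously, and a threshold crossing emits a spike,
#' resets the membrane and starts an absolute refractory period. Defaults
#' follow the common basic integrate-and-fire parameterisation
#' (tau_m 10 ms, threshold -55 mV, reset and rest -70 mV, refractory 2 ms).
#'
#' @param tau_m Membrane time constant, ms.
#' @param v_th Spike threshold, mV.
#' @param v_reset Reset potential, mV.
#' @param e_l Resting (leak) potential, mV.
#' @param t_ref Absolute refractory period, ms.
#' @return An object of class \code{lif_params}.
#' @export
lif_params <- function(tau_m = 10, v_th = -55, v_reset = -70, e_l = -70,
                       t_ref = 2) {
  stopifnot(tau_m > 0, t_ref > 0)
  if (!(v_reset <= e_l && e_l < v_th))
    stop("LIF parameters must satisfy v_reset <= e_l < v_th")
  structure(list(tau_m = tau_m, v_th = v_th, v_reset = v_reset, e_l = e_l,
                 t_ref = t_ref), class = "lif_params")
}

#' Independent external Poisson drive
#'
#' Each neuron receives an independent Poisson train of excitatory voltage
#' jumps, modelling unspecific background input.
#'
#' @param rate Poisson rate in Hz (>= 0).
#' @param amplitude Post-synaptic amplitude of one drive event, mV.
#' @return An object of class \code{external_drive}.
#' @export
external_drive <- function(rate = 10000, amplitude = 0.01) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0,
            is.numeric(amplitude), length(amplitude) == 1L)
  structure(list(rate = rate, amplitude = amplitude), class = "external_drive")
}

#' Create the state of a standalone LIF population
#'
#' A lightweight handle for simulating a population without structural
#' plasticity (no synapses unless events are injected); used for unit-level
#' checks of the electrical layer. For full networks see
#' \code{\link{run_simulation}}.
#'
#' @param n Number of neurons.
#' @param params An \code{\link{lif_params}}.
#' @param drive An \code{\link{external_drive}} (or NULL for none).
#' @param cal A \code{\link{calcium_params}}.
#' @return An object of class \code{lif_population}.
#' @export
lif_population <- function(n, params = lif_params(), drive = NULL,
                           cal = calcium_params()) {
  stopifnot(n >= 1, inherits(params, "lif_params"))
  structure(list(n = as.integer(n), params = params,
                 drive = if (is.null(drive)) external_drive(0, 0) else drive,
                 cal = cal,
                 v = rep(params$e_l, n), refrac = integer(n),
                 ca = numeric(n), step = 0),
            class = "lif_population")
}

#' Advance a standalone LIF population
#'
#' Runs \code{n_steps} integration steps of size \code{dt}. Optional external
#' events are instantaneous voltage jumps delivered at given steps (0-based,
#' relative to this call). Uses R's RNG; wrap in \code{set.seed()} for
#' reproducibility.
#'
#' @param pop A \code{\link{lif_population}}.
#' @param n_steps Number of steps.
#' @param dt Step size, ms (default 0.1).
#' @param events Optional data.frame with columns \code{step}, \code{neuron},
#'   \code{amplitude}.
#' @return A list with the updated \code{pop} and a data.frame
#'   \code{spikes(time_ms, neuron)}.
#' @export
lif_step <- function(pop, n_steps, dt = 0.1, events = NULL) {
  stopifnot(inherits(pop, "lif_population"), n_steps >= 0, dt > 0)
  if (n_steps == 0)
    return(list(pop = pop, spikes = data.frame(time_ms = numeric(0),
                                               neuron = integer(0))))
  n <- pop$n
  p <- pop$params
  if (is.null(events)) {
    ext_step <- integer(0); ext_neuron <- integer(0); ext_amp <- numeric(0)
  } else {
    o <- order(events$step)
    ext_step <- as.integer(events$step[o])
    ext_neuron <- as.integer(events$neuron[o])
    ext_amp <- as.numeric(events$amplitude[o])
  }
  ring <- matrix(0, n, 1L)
  res <- sim_interval_cpp(pop$v, pop$refrac, pop$ca, ring,
                          pop$step, as.integer(n_steps), dt,
                          integer(0), integer(0), numeric(0), integer(0), 0L,
                          rep(exp(-dt / p$tau_m), n), rep(p$e_l, n),
                          rep(p$v_th, n), rep(p$v_reset, n),
                          rep(as.integer(round(p$t_ref / dt)), n),
                          rep(pop$drive$rate * dt / 1000, n),
                          rep(pop$drive$amplitude, n),
                          rep(pop$cal$tau, n), rep(pop$cal$beta, n),
                          ext_step, ext_neuron, ext_amp, TRUE)
  pop$v <- res$v; pop$refrac <- res$refrac; pop$ca <- res$ca
  pop$step <- pop$step + n_steps
  list(pop = pop,
       spikes = data.frame(time_ms = res$spike_time, neuron = res$spike_neuron))
}

#' Fan spikes out over the synapse store
#'
#' Turns a set of spikes into delayed delivery events, one per outgoing
#' synapse of each spiking neuron, carrying the synapse's amplitude
#' (negative for inhibitory synapses) at spike time plus the synapse's delay.
#'
#' @param spikes data.frame with columns \code{time_ms} and \code{neuron}.
#' @param st A \code{\link{synapse_store}}.
#' @param dt Integration step, ms (converts stored step delays to ms).
#' @return data.frame \code{(time_ms, target, amplitude)} of pending events.
#' @export
deliver_spikes <- function(spikes, st, dt = 0.1) {
  stopifnot(inherits(st, "synapse_store"))
  ix <- seq_len(st$n)
  pre <- st$pre[ix]
  rows <- lapply(seq_len(nrow(spikes)), function(k) {
    e <- which(pre == spikes$neuron[k])
    if (length(e) == 0L) return(NULL)
    data.frame(time_ms = spikes$time_ms[k] + st$delay[e] * dt,
               target = st$post[e], amplitude = st$amp[e])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(time_ms = numeric(0), target = integer(0),
                      amplitude = numeric(0))
  out
}
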