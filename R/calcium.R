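#' Calcium trace parameters
#'
#' The per-neuron calcium concentration is a linear proxy for the mean firing
#' rate: it decays exponentially with time constant \code{tau} and is
#' incremented by \code{beta} each time the neuron fires, so that under
#' stationary Poisson firing at rate \eqn{r} (spikes/ms) its mean settles at
#' \eqn{\beta r \tau}.
#'
#' @param tau Calcium decay constant in ms. Must be positive.
#' @param beta Calcium intake per spike, in dimensionless Ca units. Must be
#'   positive.
#' @return An object of class \code{calcium_params}.
#' @examples
#' cal <- calcium_params(tau = 10000, beta = 0.001)
#' # setpoint 0.05 corresponds to 0.05 / (beta * tau) spikes/ms = 5 Hz
#' @export
calcium_params <- function(tau = 10000, beta = 0.001) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0,
            is.numeric(beta), length(beta) == 1L, beta > 0)
  structure(list(tau = tau, beta = beta), class = "calcium_params")
}

#' Calcium state of a single neuron
#'
#' Holds the current concentration and the time of the last update. The trace
#' is advanced lazily: decay is applied in closed form whenever an event
#' (spike or readout) occurs, which is exact for first-order exponential
#' decay.
#'
#' @param ca Initial concentration, Ca units (non-negative).
#' @param t Time of last update, ms.
#' @return An object of class \code{calcium_state}.
#' @export
calcium_state <- function(ca = 0, t = 0) {
  stopifnot(is.numeric(ca), length(ca) == 1L, ca >= 0, is.numeric(t))
  structure(list(ca = ca, t_last = t), class = "calcium_state")
}

#' Advance a calcium trace without spikes
#'
#' Applies the closed-form solution of dCa/dt = -Ca/tau over an interval of
#' length \code{dt}: \eqn{Ca' = Ca \, e^{-dt/\tau}}.
#'
#' @param state A \code{\link{calcium_state}}.
#' @param dt Duration in ms, non-negative.
#' @param params A \code{\link{calcium_params}}.
#' @return The updated \code{calcium_state}.
#' @export
ca_advance <- function(state, dt, params) {
  stopifnot(inherits(state, "calcium_state"), inherits(params, "calcium_params"))
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0)
    stop("'dt' must be a single non-negative number")
  state$ca <- state$ca * exp(-dt / params$tau)
  state$t_last <- state$t_last + dt
  state
}

#' Register a spike on a calcium trace
#'
#' Decays the trace from its last update time to \code{t_spike}, then adds the
#' intake constant \code{beta}.
#'
#' @param state A \code{\link{calcium_state}}.
#' @param t_spike Spike time in ms; must not precede the state's last update.
#' @param params A \code{\link{calcium_params}}.
#' @return The updated \code{calcium_state}.
#' @export
ca_on_spike <- function(state, t_spike, params) {
  stopifnot(inherits(state, "calcium_state"), inherits(params, "calcium_params"))
  if (t_spike < state$t_last)
    stop("out-of-order spike: t_spike precedes the trace's last update time")
  state <- ca_advance(state, t_spike - state$t_last, params)
  state$ca <- state$ca + params$beta
  state
}

#' Time-averaged calcium of a spike train
#'
#' Computes the exact time average of the lazily decayed trace over
#' \code{[0, t_end]} for a given spike train, by integrating the exponential
#' segments between events in closed form. Useful to relate a firing rate to
#' the calcium setpoint (mean = beta * rate * tau under Poisson firing).
#'
#' @param spike_times Increasing spike times in ms (may be empty).
#' @param t_end End of the averaging window, ms (> 0).
#' @param params A \code{\link{calcium_params}}.
#' @param ca0 Initial concentration at t = 0.
#' @return The time-averaged concentration, Ca units.
#' @export
ca_time_average <- function(spike_times, t_end, params, ca0 = 0) {
  stopifnot(inherits(params, "calcium_params"), t_end > 0)
  spike_times <- spike_times[spike_times <= t_end]
  if (is.unsorted(spike_times)) stop("'spike_times' must be non-decreasing")
  tau <- params$tau
  bounds <- c(0, spike_times, t_end)
  # concentration at the start of each segment
  ca <- ca0
  total <- 0
  for (k in seq_len(length(bounds) - 1L)) {
    d <- bounds[k + 1L] - bounds[k]
    total <- total + ca * tau * (1 - exp(-d / tau))
    ca <- ca * exp(-d / tau)
    if (k < length(bounds) - 1L) ca <- ca + params$beta  # spike at segment end
  }
  total / t_end
}
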