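#' Run a structurally plastic network simulation
#'
#' Executes the three-phase loop of the structural-plasticity algorithm:
#' (1) electrical activity and calcium are advanced at the fine integration
#' step \code{dt} for one structural interval; (2) each neuron's synaptic
#' element variables are integrated from its calcium at the interval start
#' and a fraction of vacant elements is pruned; (3) the global connectivity
#' update breaks synapses whose elements were deleted and pairs vacant
#' elements uniformly at random into new synapses. Connectivity is intended
#' to change on a timescale around 100 times slower than the electrical
#' activity; a smaller ratio triggers a warning, not an error.
#'
#' Simulated time is cumulative: a network returned by one call can be run
#' again and continues from where it stopped (useful for
#' stabilise-then-enable protocols via \code{\link{enable_plasticity}}).
#'
#' @param net An \code{\link{sp_network}}.
#' @param t_total Biological time to simulate, ms (multiple of
#'   \code{structural_interval}; 0 is a no-op).
#' @param dt Integration step, ms (default 0.1).
#' @param structural_interval Connectivity-update interval, ms; must be an
#'   integer multiple of \code{dt}.
#' @param seed Optional integer; seeds R's RNG for the whole run (spike
#'   output and edge lists are then bitwise reproducible).
#' @param record_spikes Keep the full spike raster (time, neuron).
#' @param record_neuron_calcium Also record per-neuron calcium samples
#'   (columns time_ms, neuron, ca) every \code{calcium_sampling} ms.
#' @param calcium_sampling Sampling interval for per-neuron calcium, ms;
#'   must be a multiple of \code{structural_interval}. Population means are
#'   always recorded every structural interval.
#' @param snapshot_every Optional interval (ms) at which population-pair
#'   connectivity matrices are snapshotted.
#' @param enable_plasticity_at,disable_plasticity_at Optional absolute times
#'   (ms) between which structural updates are applied, on top of the
#'   network's own plasticity flag.
#' @param check_invariants Verify element-synapse conservation after every
#'   structural interval (debug mode; slows the run).
#' @param progress Print per-second progress (synapse count and mean calcium
#'   per population).
#' @return An object of class \code{sp_run}: list with the final
#'   \code{network}, per-interval \code{calcium} means per population,
#'   per-interval synapse \code{connections} counts per rule, the
#'   \code{spikes} raster (if recorded) and connectivity \code{snapshots}.
#' @export
run_simulation <- function(net, t_total, dt = 0.1, structural_interval = 10,
                           seed = NULL, record_spikes = FALSE,
                           record_neuron_calcium = FALSE,
                           calcium_sampling = structural_interval,
                           snapshot_every = NULL,
                           enable_plasticity_at = NULL,
                           disable_plasticity_at = NULL,
                           check_invariants = FALSE, progress = FALSE) {
  stopifnot(inherits(net, "sp_network"), t_total >= 0, dt > 0)
  n_sub <- structural_interval / dt
  if (abs(n_sub - round(n_sub)) > 1e-9)
    stop("'structural_interval' must be an integer multiple of 'dt'")
  n_sub <- as.integer(round(n_sub))
  if (n_sub < 100L)
    warning("connectivity updates only ", n_sub, "x slower than the ",
            "electrical step; the model assumes a separation of around 100x")
  n_int <- t_total / structural_interval
  if (abs(n_int - round(n_int)) > 1e-9)
    stop("'t_total' must be a multiple of 'structural_interval'")
  n_int <- as.integer(round(n_int))
  if (!is.null(seed)) set.seed(seed)

  net$store <- store_clone(net$store) # value semantics for the caller
  st <- net$store
  n <- net$n

  # per-neuron electrical constants for the kernel
  decay <- exp(-dt / net$lif$tau_m)
  refsteps <- as.integer(round(net$lif$t_ref / dt))
  lambda <- net$drive$rate * dt / 1000
  delay_steps_rules <- pmax(1L, as.integer(round(net$rules$delay / dt)))
  L <- max(delay_steps_rules) + 1L
  if (st$n > 0L && max(st$delay[seq_len(st$n)]) >= L)
    stop("stored synaptic delays exceed the delivery buffer; the network ",
         "was built for a different integration step")

  if (is.null(net$state)) {
    net$state <- list(v = net$lif$e_l + numeric(n), refrac = integer(n),
                      ring = matrix(0, n, L))
  } else if (ncol(net$state$ring) != L) {
    stop("network state was created with a different delay structure")
  }
  if (is.null(net[["ca"]])) net$ca <- numeric(n)

  en_at <- if (is.null(enable_plasticity_at)) -Inf else enable_plasticity_at
  dis_at <- if (is.null(disable_plasticity_at)) Inf else disable_plasticity_at

  n_pop <- nrow(net$pop)
  ca_rec <- matrix(NA_real_, n_int, n_pop)
  conn_rec <- matrix(NA_real_, n_int, nrow(net$rules))
  t_rec <- numeric(n_int)
  spk_t <- vector("list", n_int)
  spk_i <- vector("list", n_int)
  snaps <- list()
  ca_neuron <- list()

  for (k in seq_len(n_int)) {
    t0 <- net$t_now
    start_step <- round(t0 / dt)
    ca_start <- net$ca
    res <- sim_interval_cpp(net$state$v, net$state$refrac, net$ca,
                            net$state$ring, start_step, n_sub, dt,
                            st$pre, st$post, st$amp, st$delay, st$n,
                            decay, net$lif$e_l, net$lif$v_th, net$lif$v_reset,
                            refsteps, lambda, net$drive$amp,
                            net$cal$tau, net$cal$beta,
                            integer(0), integer(0), numeric(0), record_spikes)
    net$state$v <- res$v
    net$state$refrac <- res$refrac
    net$state$ring <- res$ring
    net$ca <- res$ca
    t_end <- t0 + structural_interval
    net$t_now <- t_end
    if (record_spikes) { spk_t[[k]] <- res$spike_time; spk_i[[k]] <- res$spike_neuron }

    if (net$plasticity_enabled && t_end >= en_at && t_end < dis_at)
      net <- structural_update(net, ca_start, structural_interval, dt)
    if (check_invariants) check_conservation(net)

    t_rec[k] <- t_end
    ca_rec[k, ] <- as.vector(rowsum(net$ca, net$pop_of, reorder = TRUE)) / net$pop$size
    conn_rec[k, ] <- tabulate(st$rule[seq_len(st$n)], nbins = nrow(net$rules))
    if (record_neuron_calcium &&
        abs(t_end / calcium_sampling - round(t_end / calcium_sampling)) < 1e-9)
      ca_neuron[[length(ca_neuron) + 1L]] <-
        data.frame(time_ms = t_end, neuron = seq_len(n), ca = net$ca)
    if (!is.null(snapshot_every) &&
        abs(t_end / snapshot_every - round(t_end / snapshot_every)) < 1e-9) {
      snaps[[length(snaps) + 1L]] <-
        list(time_ms = t_end, matrix = connectivity_matrix(net))
    }
    if (progress && (t_end %% 1000 == 0))
      message(sprintf("t = %g s: %d synapses; mean Ca %s", t_end / 1000, st$n,
                      paste(sprintf("%s=%.4f", net$pop$name, ca_rec[k, ]),
                            collapse = " ")))
  }

  calcium <- data.frame(
    time_ms = rep(t_rec, n_pop),
    population = rep(net$pop$name, each = n_int),
    ca_mean = as.vector(ca_rec))
  connections <- data.frame(
    time_ms = rep(t_rec, nrow(net$rules)),
    label = rep(net$rules$label, each = n_int),
    count = as.vector(conn_rec))
  spikes <- if (record_spikes)
    data.frame(time_ms = unlist(spk_t), neuron = unlist(spk_i))
  else NULL

  structure(list(network = net, calcium = calcium, connections = connections,
                 spikes = spikes, snapshots = snaps,
                 calcium_neuron = if (record_neuron_calcium)
                   do.call(rbind, ca_neuron) else NULL,
                 dt = dt, structural_interval = structural_interval),
            class = "sp_run")
}

#' @export
print.sp_run <- function(x, ...) {
  net <- x$network
  cat("Structural-plasticity run up to t =", net$t_now / 1000, "s;",
      store_count(net$store), "synapses\n")
  if (nrow(x$calcium)) {
    last <- x$calcium[x$calcium$time_ms == max(x$calcium$time_ms), ]
    cat("Final mean calcium:",
        paste(sprintf("%s=%.4f", last$population, last$ca_mean),
              collapse = ", "), "\n")
  }
  invisible(x)
}
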