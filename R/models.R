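#' Build the two-population self-organizing network
#'
#' A network of leaky integrate-and-fire neurons, 80% excitatory and 20%
#' inhibitory, that starts with zero synapses and wires itself under
#' Gaussian homeostatic growth curves. Excitatory neurons grow
#' \code{Axon_ex}, \code{Den_ex} and \code{Den_in} elements with calcium
#' setpoint \eqn{\epsilon = 0.05} (5 Hz for the default calcium constants);
#' inhibitory neurons grow \code{Axon_in}, \code{Den_ex} and \code{Den_in}
#' with setpoint \eqn{\epsilon = 0.2} (20 Hz). All growth rates are
#' \eqn{\nu = 10^{-4}} elements/ms except the excitatory dendritic elements
#' of the inhibitory population, which grow at \eqn{4 \times 10^{-4}} so the
#' more active inhibitory population offers enough excitatory contact points
#' early on. Two plastic synapse rules connect the elements:
#' \code{Axon_ex -> Den_ex} at +1 mV and \code{Axon_in -> Den_in} at
#' \code{-g} mV.
#'
#' At full size (\code{scale = 1}) the network has 1000 neurons and
#' self-organizes over thousands of biological seconds; smaller scales with
#' \code{nu_scale} of 5-10 reproduce the same homeostatic convergence within
#' a few biological minutes on a desk machine.
#'
#' Every neuron receives an independent Poisson background drive. Because
#' the Gaussian growth rule is exactly zero at \eqn{Ca = \eta = 0}, a fully
#' silent network is a (marginal) fixed point: some spontaneous activity is
#' required to seed element growth. The default drive amplitude is therefore
#' calibrated so that disconnected neurons fire spontaneously at around
#' 1 Hz, well below both setpoints; see the package vignette.
#'
#' @param scale Size multiplier (1 = 1000 neurons). Must leave at least two
#'   neurons in each population.
#' @param nu_scale Multiplier on all growth rates (shortens convergence at
#'   small scale).
#' @param drive An \code{\link{external_drive}} applied to every neuron.
#' @param g Relative strength of inhibitory synapses (amplitude \code{-g} mV).
#' @param neuron,cal LIF and calcium parameters shared by all neurons.
#' @param prune_fraction,allow_autapses Passed to \code{\link{sp_network}}.
#' @return An \code{\link{sp_network}} with zero synapses.
#' @export
build_two_population <- function(scale = 1, nu_scale = 1,
                                 drive = external_drive(10000, 0.122),
                                 g = 1,
                                 neuron = lif_params(),
                                 cal = calcium_params(tau = 10000, beta = 0.001),
                                 prune_fraction = 0,
                                 allow_autapses = FALSE) {
  stopifnot(scale > 0, nu_scale > 0, g >= 0)
  n <- round(1000 * scale)
  n_e <- round(0.8 * n)
  n_i <- n - n_e
  if (n_e < 2 || n_i < 2)
    stop("scale too small: each population needs at least 2 neurons")
  nu <- 1e-4 * nu_scale
  gc_e <- growth_curve("gaussian", nu = nu, eps = 0.05, eta = 0)
  gc_i <- growth_curve("gaussian", nu = nu, eps = 0.2, eta = 0)
  gc_i_denex <- growth_curve("gaussian", nu = 4e-4 * nu_scale, eps = 0.2, eta = 0)
  pops <- list(
    population_spec("excitatory", n_e,
                    elements = list(Axon_ex = gc_e, Den_ex = gc_e, Den_in = gc_e),
                    neuron = neuron, drive = drive, cal = cal),
    population_spec("inhibitory", n_i,
                    elements = list(Axon_in = gc_i, Den_ex = gc_i_denex,
                                    Den_in = gc_i),
                    neuron = neuron, drive = drive, cal = cal))
  rules <- list(
    synapse_rule("synapse_ex", "Axon_ex", "Den_ex", amplitude = 1.0),
    synapse_rule("synapse_in", "Axon_in", "Den_in", amplitude = -g))
  sp_network(pops, rules, prune_fraction = prune_fraction,
             allow_autapses = allow_autapses)
}

mc_population_names <- c("L23e", "L23i", "L4e", "L4i", "L5e", "L5i",
                         "L6e", "L6i")

#' Build the eight-population cortical-microcircuit network
#'
#' Four layers (2/3, 4, 5, 6), each with one excitatory and one inhibitory
#' population of LIF neurons, with per-population Gaussian growth curves and
#' calcium setpoints supplied by a parameter file. The package ships a
#' documented parameter file of illustrative defaults
#' (\code{system.file("extdata", "microcircuit_params.yaml",
#' package = "mspnet")}): population sizes follow the published counts of
#' the cortical-microcircuit model this layout is based on, while the
#' per-population setpoints are illustrative (excitatory below inhibitory in
#' every layer, layer 2/3 lowest) because the growth-curve parameters of the
#' original study are not published numerically.
#'
#' @param scale Size multiplier applied to all population sizes.
#' @param connectivity_init \code{"empty"} starts fully disconnected;
#'   \code{"reference"} pre-connects the network by sampling each
#'   population-pair's synapse count from \code{conn_table};
#'   \code{"perturbed"} first jitters every table entry uniformly by
#'   \code{±perturbation} (relative) and then samples.
#' @param params Path to a YAML parameter file, or an already-parsed list.
#' @param conn_table 8x8 numeric matrix of connection probabilities
#'   (source population in rows, target in columns, named by population);
#'   required for the pre-connected initialisations. The reference table of
#'   the original microcircuit study is not bundled; supply your own.
#' @param perturbation Relative jitter for \code{"perturbed"} (0.1 = 10%).
#' @param nu_scale Multiplier on all growth rates.
#' @param drive Optional \code{\link{external_drive}} overriding the file's.
#' @return An \code{\link{sp_network}}.
#' @export
build_microcircuit <- function(scale = 1,
                               connectivity_init = c("empty", "reference",
                                                     "perturbed"),
                               params = NULL, conn_table = NULL,
                               perturbation = 0.1, nu_scale = 1,
                               drive = NULL) {
  connectivity_init <- match.arg(connectivity_init)
  if (is.null(params))
    params <- system.file("extdata", "microcircuit_params.yaml",
                          package = "mspnet")
  cfg <- if (is.character(params)) yaml::read_yaml(params) else params
  missing_pops <- setdiff(mc_population_names, names(cfg$populations))
  if (length(missing_pops))
    stop("parameter file lacks entries for population(s): ",
         paste(missing_pops, collapse = ", "))
  net <- network_from_config(cfg, scale = scale, nu_scale = nu_scale,
                             drive = drive,
                             population_order = mc_population_names)
  if (connectivity_init != "empty") {
    if (is.null(conn_table))
      stop("'conn_table' is required for pre-connected initialisation")
    tab <- as.matrix(conn_table)
    if (!identical(dim(tab), c(8L, 8L)) ||
        !identical(rownames(tab), mc_population_names) ||
        !identical(colnames(tab), mc_population_names))
      stop("'conn_table' must be an 8x8 matrix with populations ",
           paste(mc_population_names, collapse = ", "), " as row/col names")
    if (connectivity_init == "perturbed")
      tab <- tab * (1 + stats::runif(length(tab), -perturbation, perturbation))
    net <- preconnect_from_table(net, tab)
  }
  net
}

#' Build a network from a configuration list or YAML file
#'
#' The configuration mirrors the dictionary layout used to set up structural
#' plasticity in spiking simulators: named growth-curve dictionaries with
#' keys \code{growth_curve}, \code{growth_rate}, \code{eta}, \code{eps} and
#' \code{continuous} attached to named element types per population, plus
#' synapse models naming their \code{pre_synaptic_element} and
#' \code{post_synaptic_element}.
#'
#' @param cfg Parsed configuration list (or path to a YAML file).
#' @param scale Multiplier on population sizes.
#' @param nu_scale Multiplier on growth rates.
#' @param drive Optional \code{\link{external_drive}} overriding the config.
#' @param population_order Optional character vector fixing population order.
#' @return An \code{\link{sp_network}}.
#' @export
network_from_config <- function(cfg, scale = 1, nu_scale = 1, drive = NULL,
                                population_order = NULL) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg), !is.null(cfg$populations), !is.null(cfg$synapses))
  cal_default <- do.call(calcium_params, as.list(cfg$calcium %||% list()))
  lif_default <- do.call(lif_params, as.list(cfg$neuron %||% list()))
  drv_cfg <- cfg$drive %||% list()
  drive_default <- drive %||% do.call(external_drive, as.list(drv_cfg))
  pop_names <- population_order %||% names(cfg$populations)
  pops <- lapply(pop_names, function(nm) {
    p <- cfg$populations[[nm]]
    size <- max(2L, round(p$size * scale))
    elems <- lapply(p$elements, function(e) {
      growth_curve(kind = e$growth_curve %||% "gaussian",
                   nu = (e$growth_rate) * nu_scale,
                   eps = e$eps, eta = e$eta %||% 0,
                   continuous = isTRUE(e$continuous))
    })
    pdrive <- if (!is.null(drive)) drive
      else if (!is.null(p$drive)) do.call(external_drive, as.list(p$drive))
      else drive_default
    population_spec(nm, size, elements = elems, neuron = lif_default,
                    drive = pdrive, cal = cal_default)
  })
  rules <- lapply(names(cfg$synapses), function(lbl) {
    s <- cfg$synapses[[lbl]]
    synapse_rule(lbl, s$pre_synaptic_element, s$post_synaptic_element,
                 amplitude = s$amplitude, delay = s$delay %||% 1.0,
                 plastic = !isFALSE(s$plastic))
  })
  sp_network(pops, rules,
             prune_fraction = cfg$prune_fraction %||% 0,
             allow_autapses = isTRUE(cfg$allow_autapses))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pre-connect a network from a population-pair connection-probability table:
# expected synapse count round(p * N_src * N_tgt) per pair, endpoints drawn
# uniformly within each population (multapses allowed). Element variables
# are initialised to exactly the bound counts (z = connected, no vacancies).
preconnect_from_table <- function(net, tab) {
  exc_rule <- which(net$rules$amplitude > 0)[1]
  inh_rule <- which(net$rules$amplitude < 0)[1]
  for (i in seq_len(nrow(tab))) {
    src <- which(net$pop$name == rownames(tab)[i])
    is_exc <- grepl("e$", rownames(tab)[i])
    r <- if (is_exc) exc_rule else inh_rule
    for (j in seq_len(ncol(tab))) {
      tgt <- which(net$pop$name == colnames(tab)[j])
      n_syn <- round(tab[i, j] * net$pop$size[src] * net$pop$size[tgt])
      if (n_syn <= 0) next
      a <- sample.int(net$pop$size[src], n_syn, replace = TRUE) +
        net$pop$first[src] - 1L
      b <- sample.int(net$pop$size[tgt], n_syn, replace = TRUE) +
        net$pop$first[tgt] - 1L
      if (!net$config$allow_autapses) {
        bad <- a == b
        b[bad] <- net$pop$first[tgt] - 1L +
          (b[bad] %% net$pop$size[tgt]) + 1L # deterministic shift off-diagonal
        still <- a == b
        a <- a[!still]; b <- b[!still]
      }
      delay_steps <- max(1L, as.integer(round(net$rules$delay[r] / 0.1)))
      store_add(net$store, a, b, r, net$rules$amplitude[r], delay_steps)
      inc <- tabulate(c(net$elem_idx[cbind(net$rules$pre_type[r], a)],
                        net$elem_idx[cbind(net$rules$post_type[r], b)]),
                      nbins = length(net$elem$neuron))
      net$elem$connected <- net$elem$connected + as.integer(inc)
    }
  }
  net$elem$z <- as.numeric(net$elem$connected)
  net
}
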