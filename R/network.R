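#' Specify one neuron population
#'
#' @param name Population name.
#' @param size Number of neurons (> 0).
#' @param elements Named list of \code{\link{growth_curve}} objects, one per
#'   synaptic-element type this population grows (e.g. \code{Axon_ex},
#'   \code{Den_ex}, \code{Den_in}).
#' @param neuron An \code{\link{lif_params}}.
#' @param drive An \code{\link{external_drive}}.
#' @param cal A \code{\link{calcium_params}}.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(name, size, elements, neuron = lif_params(),
                            drive = external_drive(), cal = calcium_params()) {
  stopifnot(is.character(name), length(name) == 1L, size > 0,
            is.list(elements), length(elements) > 0,
            !is.null(names(elements)), all(nzchar(names(elements))))
  lapply(elements, function(e) stopifnot(inherits(e, "growth_curve")))
  structure(list(name = name, size = as.integer(size), elements = elements,
                 neuron = neuron, drive = drive, cal = cal),
            class = "population_spec")
}

#' Specify a structurally plastic synapse type
#'
#' A rule names the pre- and post-synaptic element types it binds and the
#' electrical properties of the synapses it creates. During every
#' connectivity update, vacant elements of the rule's pre and post types are
#' paired uniformly at random to form new synapses of this type.
#'
#' @param label Synapse model label (e.g. "synapse_ex").
#' @param pre_element Pre-synaptic (axonal) element type.
#' @param post_element Post-synaptic (dendritic) element type.
#' @param amplitude Post-synaptic amplitude in mV (negative for inhibitory).
#' @param delay Synaptic delay in ms (must be >= the integration step).
#' @param plastic If FALSE the rule's synapses are never rewired.
#' @return An object of class \code{synapse_rule}.
#' @export
synapse_rule <- function(label, pre_element, post_element, amplitude,
                         delay = 1.0, plastic = TRUE) {
  stopifnot(is.character(label), is.character(pre_element),
            is.character(post_element), is.numeric(amplitude), delay > 0)
  structure(list(label = label, pre_element = pre_element,
                 post_element = post_element, amplitude = amplitude,
                 delay = delay, plastic = isTRUE(plastic)),
            class = "synapse_rule")
}

#' Assemble a structurally plastic network
#'
#' Builds the full network object from population specs and synapse rules:
#' flat per-neuron parameter vectors for the electrical layer, a per-neuron
#' per-element-type table of continuous element variables, and an (initially
#' empty) global synapse store.
#'
#' @param populations List of \code{\link{population_spec}} objects.
#' @param rules List of \code{\link{synapse_rule}} objects.
#' @param prune_fraction Fraction of vacant elements removed at every
#'   structural update (see \code{\link{prune_vacant}}).
#' @param allow_autapses Permit self-connections when pairing elements.
#' @return An object of class \code{sp_network}.
#' @export
sp_network <- function(populations, rules, prune_fraction = 0,
                       allow_autapses = FALSE) {
  stopifnot(length(populations) > 0, length(rules) > 0)
  lapply(populations, function(p) stopifnot(inherits(p, "population_spec")))
  lapply(rules, function(r) stopifnot(inherits(r, "synapse_rule")))
  sizes <- vapply(populations, `[[`, integer(1), "size")
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate population names")
  n <- sum(sizes)
  last <- cumsum(sizes)
  first <- last - sizes + 1L
  pop <- data.frame(name = nm, size = sizes, first = first, last = last,
                    stringsAsFactors = FALSE)
  pop_of <- rep.int(seq_along(sizes), sizes)

  # per-neuron electrical / calcium / drive parameter vectors
  fld <- function(get) unlist(lapply(seq_along(populations), function(k)
    rep(get(populations[[k]]), sizes[k])))
  lif <- list(tau_m = fld(function(p) p$neuron$tau_m),
              v_th = fld(function(p) p$neuron$v_th),
              v_reset = fld(function(p) p$neuron$v_reset),
              e_l = fld(function(p) p$neuron$e_l),
              t_ref = fld(function(p) p$neuron$t_ref))
  cal <- list(tau = fld(function(p) p$cal$tau),
              beta = fld(function(p) p$cal$beta))
  drive <- list(rate = fld(function(p) p$drive$rate),
                amp = fld(function(p) p$drive$amplitude))

  # element table: one row per (neuron, element type)
  types <- unique(unlist(lapply(populations, function(p) names(p$elements))))
  en <- integer(0); et <- integer(0)
  kind <- character(0); nu <- numeric(0); eps <- numeric(0); eta <- numeric(0)
  for (k in seq_along(populations)) {
    p <- populations[[k]]
    ids <- first[k]:last[k]
    for (tname in names(p$elements)) {
      g <- p$elements[[tname]]
      en <- c(en, ids)
      et <- c(et, rep(match(tname, types), length(ids)))
      kind <- c(kind, rep(g$kind, length(ids)))
      nu <- c(nu, rep(g$nu, length(ids)))
      eps <- c(eps, rep(g$eps, length(ids)))
      eta <- c(eta, rep(ifelse(is.na(g$eta), 0, g$eta), length(ids)))
    }
  }
  elem <- list(neuron = en, type = et, z = numeric(length(en)),
               connected = integer(length(en)),
               kind = kind, nu = nu, eps = eps, eta = eta)
  # (type, neuron) -> element row lookup
  elem_idx <- matrix(NA_integer_, nrow = length(types), ncol = n)
  elem_idx[cbind(et, en)] <- seq_along(en)

  rl <- data.frame(label = vapply(rules, `[[`, character(1), "label"),
                   pre_type = match(vapply(rules, `[[`, character(1), "pre_element"), types),
                   post_type = match(vapply(rules, `[[`, character(1), "post_element"), types),
                   amplitude = vapply(rules, `[[`, numeric(1), "amplitude"),
                   delay = vapply(rules, `[[`, numeric(1), "delay"),
                   plastic = vapply(rules, `[[`, logical(1), "plastic"),
                   stringsAsFactors = FALSE)
  if (anyNA(rl$pre_type) || anyNA(rl$post_type))
    stop("synapse rule references element types not declared on any population: ",
         paste(setdiff(c(vapply(rules, `[[`, character(1), "pre_element"),
                         vapply(rules, `[[`, character(1), "post_element")),
                       types), collapse = ", "))

  net <- structure(list(
    n = n, pop = pop, pop_of = pop_of, lif = lif, cal = cal,
    ca = numeric(n), drive = drive,
    types = types, elem = elem, elem_idx = elem_idx, rules = rl,
    store = synapse_store(),
    config = list(prune_fraction = prune_fraction,
                  allow_autapses = isTRUE(allow_autapses)),
    plasticity_enabled = TRUE,
    t_now = 0, state = NULL), class = "sp_network")
  net
}

#' @export
print.sp_network <- function(x, ...) {
  cat("Structurally plastic network:", x$n, "neurons,",
      nrow(x$pop), "population(s),", store_count(x$store), "synapses",
      sprintf("(t = %g ms)\n", x$t_now))
  cat("Populations:", paste(sprintf("%s[%d]", x$pop$name, x$pop$size),
                            collapse = ", "), "\n")
  cat("Rules:", paste(sprintf("%s (%s->%s, %+.2f mV)", x$rules$label,
                              x$types[x$rules$pre_type],
                              x$types[x$rules$post_type],
                              x$rules$amplitude), collapse = "; "), "\n")
  invisible(x)
}

#' Enable or disable structural plasticity
#'
#' While disabled, the electrical simulation and calcium tracking continue
#' (the traces are needed if plasticity is later re-enabled) but element
#' integration, pruning and all connectivity changes are skipped, so the
#' edge set is frozen.
#'
#' @param net An \code{\link{sp_network}}.
#' @return The updated network.
#' @export
enable_plasticity <- function(net) {
  stopifnot(inherits(net, "sp_network"))
  net$plasticity_enabled <- TRUE
  net
}

#' @rdname enable_plasticity
#' @export
disable_plasticity <- function(net) {
  stopifnot(inherits(net, "sp_network"))
  net$plasticity_enabled <- FALSE
  net
}

#' Delete synapses manually
#'
#' Removes the given edges (by index into \code{\link{store_edges}} order)
#' irrespective of plasticity. Both endpoint elements survive and become
#' vacant, so they can be re-matched at the next connectivity update.
#'
#' @param net An \code{\link{sp_network}}.
#' @param idx Edge indices to remove.
#' @return The updated network.
#' @export
delete_synapses <- function(net, idx) {
  stopifnot(inherits(net, "sp_network"))
  st <- net$store
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > st$n)) stop("edge index out of range")
  r <- st$rule[idx]
  rows <- c(net$elem_idx[cbind(net$rules$pre_type[r], st$pre[idx])],
            net$elem_idx[cbind(net$rules$post_type[r], st$post[idx])])
  dec <- tabulate(rows, nbins = length(net$elem$neuron))
  net$elem$connected <- net$elem$connected - as.integer(dec)
  if (any(net$elem$connected < 0)) stop("bookkeeping error: negative connected count")
  store_delete_idx(st, idx)
  net
}

#' Check element-synapse conservation
#'
#' For every element type, the number of connected elements summed over
#' neurons must equal the number of edge endpoints of that type in the
#' synapse store. Violations indicate a bookkeeping bug in the plasticity
#' manager.
#'
#' @param net An \code{\link{sp_network}}.
#' @return TRUE invisibly if consistent, otherwise an error is raised.
#' @export
check_conservation <- function(net) {
  stopifnot(inherits(net, "sp_network"))
  st <- net$store
  ix <- seq_len(st$n)
  r <- st$rule[ix]
  endpoint <- tabulate(c(net$rules$pre_type[r], net$rules$post_type[r]),
                       nbins = length(net$types))
  bound <- vapply(seq_along(net$types), function(tt)
    sum(net$elem$connected[net$elem$type == tt]), numeric(1))
  if (!isTRUE(all.equal(as.numeric(endpoint), bound)))
    stop("element-synapse conservation violated: endpoints ",
         paste(endpoint, collapse = "/"), " vs connected ",
         paste(bound, collapse = "/"))
  if (any(net$elem$connected < 0)) stop("negative connected count")
  if (any(net$elem$connected > floor(pmax(net$elem$z, 0)) + 1e-9)) {
    # allowed transiently only inside a structural update, never between them
    stop("connected count exceeds available elements")
  }
  invisible(TRUE)
}
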