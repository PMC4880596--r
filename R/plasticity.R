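#' Per-neuron structural report
#'
#' Summarises, for every (neuron, element type) pair, how many vacant
#' elements are available for synapse formation and how many connected
#' elements must be released because the element variable fell below the
#' number of bound elements. This is the information the connectivity
#' manager needs at each structural interval; vacancies and deletions are
#' never netted against each other across element types.
#'
#' @param net An \code{\link{sp_network}}.
#' @param n_deleted Optional integer vector (one entry per element-table row)
#'   of deletions requested by the most recent element integration; defaults
#'   to the excess of connected over available elements.
#' @return data.frame (neuron, type, type_name, n_vacant, n_to_delete),
#'   restricted to rows where either count is positive.
#' @export
build_reports <- function(net, n_deleted = NULL) {
  stopifnot(inherits(net, "sp_network"))
  e <- net$elem
  f <- floor(pmax(e$z, 0))
  n_vacant <- pmax(0L, as.integer(f) - e$connected)
  if (is.null(n_deleted)) {
    n_to_delete <- pmax(0L, e$connected - as.integer(f))
  } else {
    stopifnot(length(n_deleted) == length(e$neuron))
    n_to_delete <- as.integer(n_deleted)
  }
  keep <- n_vacant > 0L | n_to_delete > 0L
  data.frame(neuron = e$neuron[keep], type = e$type[keep],
             type_name = net$types[e$type[keep]],
             n_vacant = n_vacant[keep], n_to_delete = n_to_delete[keep])
}

#' Break synapses for deleted elements
#'
#' For every neuron that must release \code{n_to_delete} elements of a given
#' type, that many of its synapses using this element type are sampled
#' uniformly at random without replacement and removed. The partner neuron's
#' counterpart element survives: its connected count is decremented so it
#' becomes vacant (its element variable is unchanged) and can be re-matched
#' at the \emph{next} connectivity update. If an earlier deletion in the same
#' interval already removed a synapse that this neuron would have had to
#' release, the request is capped at the remaining excess (no double-free).
#'
#' @param net An \code{\link{sp_network}}.
#' @param report A report as produced by \code{\link{build_reports}} (only
#'   its \code{n_to_delete} entries are used).
#' @return The updated network.
#' @export
commit_deletions <- function(net, report) {
  stopifnot(inherits(net, "sp_network"))
  del <- report[report$n_to_delete > 0L, , drop = FALSE]
  if (nrow(del) == 0L) return(net)
  st <- net$store
  ne <- st$n
  ix <- seq_len(ne)
  pre <- st$pre[ix]; post <- st$post[ix]; rl <- st$rule[ix]
  pre_t <- net$rules$pre_type[rl]
  post_t <- net$rules$post_type[rl]
  alive <- rep(TRUE, ne)
  for (k in seq_len(nrow(del))) {
    i <- del$neuron[k]; tt <- del$type[k]
    row <- net$elem_idx[tt, i]
    need <- del$n_to_delete[k]
    if (is.na(row) || need > net$elem$connected[row])
      stop("deletion report exceeds connected count for neuron ", i,
           " element ", net$types[tt])
    cand <- which(alive & ((pre == i & pre_t == tt) | (post == i & post_t == tt)))
    # cap at the edges still alive: an earlier deletion in this interval may
    # already have removed a synapse this element was bound in (no double-free)
    need <- min(need, length(cand))
    if (need > 0L) {
      sel <- if (length(cand) == 1L) cand else sample(cand, need)
      alive[sel] <- FALSE
    }
  }
  kill <- which(!alive)
  if (length(kill)) net <- delete_synapses(net, kill)
  net
}

#' Form synapses by uniform random pairing of vacant elements
#'
#' For every plastic synapse rule, the vacancy counts are expanded into two
#' sequences (one entry per vacant pre element and one per vacant post
#' element), both are shuffled independently, and entries are paired
#' positionally for \code{min(length(pre), length(post))} pairs, so the
#' probability of two neurons connecting depends solely on how many
#' compatible vacant elements they offer. Pairs that would create a
#' forbidden autapse are skipped (both elements stay vacant for the next
#' interval). Repeated pairs create parallel synapses (multapses).
#'
#' @param net An \code{\link{sp_network}}.
#' @param vacancies data.frame (neuron, type, n_vacant) as from
#'   \code{\link{build_reports}}; vacancy counts are consumed in rule order
#'   if several rules share an element type.
#' @param dt Integration step in ms used to convert rule delays to steps.
#' @return The updated network.
#' @export
form_synapses <- function(net, vacancies, dt = 0.1) {
  stopifnot(inherits(net, "sp_network"))
  vac <- vacancies[vacancies$n_vacant > 0L, , drop = FALSE]
  if (nrow(vac) == 0L) return(net)
  # remaining vacancies indexed by element-table row
  rows <- net$elem_idx[cbind(vac$type, vac$neuron)]
  remaining <- integer(length(net$elem$neuron))
  remaining[rows] <- vac$n_vacant
  for (r in which(net$rules$plastic)) {
    pre_rows <- which(net$elem$type == net$rules$pre_type[r] & remaining > 0L)
    post_rows <- which(net$elem$type == net$rules$post_type[r] & remaining > 0L)
    if (!length(pre_rows) || !length(post_rows)) next
    pre_seq <- rep.int(net$elem$neuron[pre_rows], remaining[pre_rows])
    post_seq <- rep.int(net$elem$neuron[post_rows], remaining[post_rows])
    pre_seq <- pre_seq[sample.int(length(pre_seq))]
    post_seq <- post_seq[sample.int(length(post_seq))]
    m <- min(length(pre_seq), length(post_seq))
    if (m == 0L) next
    a <- pre_seq[seq_len(m)]
    b <- post_seq[seq_len(m)]
    if (!net$config$allow_autapses) {
      ok <- a != b
      a <- a[ok]; b <- b[ok]
    }
    if (!length(a)) next
    delay_steps <- max(1L, as.integer(round(net$rules$delay[r] / dt)))
    store_add(net$store, a, b, r, net$rules$amplitude[r], delay_steps)
    inc <- tabulate(c(net$elem_idx[cbind(net$rules$pre_type[r], a)],
                      net$elem_idx[cbind(net$rules$post_type[r], b)]),
                    nbins = length(remaining))
    net$elem$connected <- net$elem$connected + as.integer(inc)
    remaining <- remaining - as.integer(inc) # matched vacancies are consumed
  }
  net
}

# One full structural update: integrate element variables from the calcium
# at the interval start, prune vacant elements, build the global report,
# break synapses for deleted elements, then pair vacant elements into new
# synapses. Deletion-freed counterparts are excluded from this interval's
# formation pool (the vacancy counts are taken before deletions commit).
structural_update <- function(net, ca_start, dt_struct, dt = 0.1) {
  e <- net$elem
  dz <- element_delta(e$kind, e$nu, e$eps, e$eta,
                      ca_start[e$neuron], dt_struct, net$cal$tau[e$neuron])
  f_old <- floor(pmax(e$z, 0))
  z_new <- e$z + dz
  f_new <- floor(pmax(z_new, 0))
  n_del <- pmax(0L, e$connected - as.integer(f_new))
  # prune a fraction of the vacant elements (continuous reduction of z)
  vac_now <- pmax(0, f_new - e$connected)
  z_new <- z_new - net$config$prune_fraction * vac_now
  net$elem$z <- z_new
  rep <- build_reports(net, n_deleted = n_del)
  net <- commit_deletions(net, rep)
  net <- form_synapses(net, rep, dt = dt)
  net
}
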