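#' Create an empty synapse store
#'
#' The store is the global edge list of the network: a multiset of
#' (pre neuron, post neuron, rule, amplitude, delay) tuples. Parallel edges
#' between the same pair (multapses) are allowed and kept as separate
#' entries. Internally it is an environment with pre-allocated columns and
#' amortised growth, so edge insertion and deletion are cheap even for
#' hundreds of thousands of synapses; edge order carries no meaning.
#'
#' @param capacity Initial capacity (grown automatically).
#' @return An object of class \code{synapse_store}.
#' @export
synapse_store <- function(capacity = 1024L) {
  st <- new.env(parent = emptyenv())
  st$pre <- integer(capacity)
  st$post <- integer(capacity)
  st$rule <- integer(capacity)
  st$amp <- numeric(capacity)
  st$delay <- integer(capacity) # delay in integration steps
  st$n <- 0L
  class(st) <- "synapse_store"
  st
}

#' @rdname synapse_store
#' @param st A \code{synapse_store}.
#' @export
store_count <- function(st) st$n

store_grow <- function(st, need) {
  cap <- length(st$pre)
  if (st$n + need <= cap) return(invisible(st))
  newcap <- max(2L * cap, st$n + need)
  for (f in c("pre", "post", "rule")) {
    v <- st[[f]]
    length(v) <- newcap
    v[is.na(v)] <- 0L
    st[[f]] <- v
  }
  for (f in c("amp")) {
    v <- st[[f]]; length(v) <- newcap; v[is.na(v)] <- 0; st[[f]] <- v
  }
  v <- st$delay; length(v) <- newcap; v[is.na(v)] <- 0L; st$delay <- v
  invisible(st)
}

store_add <- function(st, pre, post, rule, amp, delay) {
  k <- length(pre)
  if (k == 0L) return(invisible(st))
  store_grow(st, k)
  ix <- st$n + seq_len(k)
  st$pre[ix] <- as.integer(pre)
  st$post[ix] <- as.integer(post)
  st$rule[ix] <- as.integer(rule)
  st$amp[ix] <- rep_len(amp, k)
  st$delay[ix] <- rep_len(as.integer(delay), k)
  st$n <- st$n + k
  invisible(st)
}

# delete edges by index (1..n); order of remaining edges is not preserved
store_delete_idx <- function(st, idx) {
  if (length(idx) == 0L) return(invisible(st))
  idx <- sort(unique(as.integer(idx)), decreasing = TRUE)
  for (i in idx) {
    if (i < st$n) {
      st$pre[i] <- st$pre[st$n]
      st$post[i] <- st$post[st$n]
      st$rule[i] <- st$rule[st$n]
      st$amp[i] <- st$amp[st$n]
      st$delay[i] <- st$delay[st$n]
    }
    st$n <- st$n - 1L
  }
  invisible(st)
}

store_clone <- function(st) {
  st2 <- synapse_store(max(1L, length(st$pre)))
  for (f in c("pre", "post", "rule", "amp", "delay", "n")) st2[[f]] <- st[[f]]
  st2
}

#' Edge list of a synapse store as a data frame
#'
#' @param st A \code{synapse_store}.
#' @param rules Optional rule table (as held by a network) used to attach
#'   rule labels.
#' @return A data.frame with columns pre, post, rule (index), amplitude,
#'   delay_steps, and label if \code{rules} is given.
#' @export
store_edges <- function(st, rules = NULL) {
  ix <- seq_len(st$n)
  out <- data.frame(pre = st$pre[ix], post = st$post[ix], rule = st$rule[ix],
                    amplitude = st$amp[ix], delay_steps = st$delay[ix])
  if (!is.null(rules)) out$label <- rules$label[out$rule]
  out
}
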