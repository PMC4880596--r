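#' Population-pair connectivity matrix
#'
#' Counts the synapses between every ordered pair of populations (source in
#' rows, target in columns) at the network's current state.
#'
#' @param net An \code{\link{sp_network}}.
#' @return Integer matrix with population names on rows and columns and an
#'   attribute \code{sizes} holding the population sizes.
#' @export
connectivity_matrix <- function(net) {
  stopifnot(inherits(net, "sp_network"))
  st <- net$store
  ix <- seq_len(st$n)
  n_pop <- nrow(net$pop)
  m <- matrix(0L, n_pop, n_pop,
              dimnames = list(net$pop$name, net$pop$name))
  if (st$n > 0) {
    sp <- net$pop_of[st$pre[ix]]
    tp <- net$pop_of[st$post[ix]]
    tab <- table(factor(sp, levels = seq_len(n_pop)),
                 factor(tp, levels = seq_len(n_pop)))
    m[] <- as.integer(tab)
  }
  attr(m, "sizes") <- stats::setNames(net$pop$size, net$pop$name)
  m
}

#' Percent connectivity
#'
#' Normalizes a population-pair synapse-count matrix to percentages for
#' comparison against a reference connectivity map. Two readings of
#' "percent connectivity" are supported: \code{"share"} (default) expresses
#' each pair's count as a percentage of all synapses in the network, so the
#' matrix sums to 100; \code{"pair-probability"} expresses each entry as
#' \code{100 * count / (N_src * N_tgt)}, the percent connection probability
#' of the pair (requires population sizes).
#'
#' @param m Count matrix as from \code{\link{connectivity_matrix}}.
#' @param normalization "share" or "pair-probability".
#' @param sizes Named population sizes; defaults to the matrix's
#'   \code{sizes} attribute.
#' @return Numeric matrix of percentages with the same dimnames.
#' @export
percent_connectivity <- function(m, normalization = c("share", "pair-probability"),
                                 sizes = attr(m, "sizes")) {
  normalization <- match.arg(normalization)
  m <- as.matrix(m)
  if (sum(m) == 0) stop("empty network: no synapses to normalize")
  if (normalization == "share") {
    out <- 100 * m / sum(m)
  } else {
    if (is.null(sizes)) stop("population sizes required for pair-probability")
    sizes <- sizes[rownames(m)]
    out <- 100 * m / outer(sizes, sizes)
  }
  attr(out, "sizes") <- sizes
  out
}

#' Average error between two percent-connectivity matrices
#'
#' Elementwise absolute differences between two same-shaped, same-labelled
#' percentage matrices; returns their mean and standard deviation over all
#' entries. Symmetric in its arguments.
#'
#' @param a,b Percent matrices with identical dimnames.
#' @return List with components \code{mean} and \code{sd}.
#' @export
average_error <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) || !identical(dimnames(a), dimnames(b)))
    stop("matrices must have identical shape and population labels")
  d <- abs(a - b)
  list(mean = mean(d), sd = stats::sd(as.vector(d)))
}

#' Summarise calcium trajectories and convergence
#'
#' For each population, smooths the recorded mean-calcium trace with a
#' running mean over \code{window} ms and reports the convergence time: the
#' first time from which the running mean stays within \code{band}
#' (a fraction of the setpoint) of the population's target for the rest of
#' the recording. Populations whose smoothed trace never settles in the band
#' are reported as not converged.
#'
#' @param calcium data.frame \code{(time_ms, population, ca_mean)} as
#'   recorded by \code{\link{run_simulation}} (regular sampling).
#' @param eps Named vector of calcium setpoints per population.
#' @param band Half-width of the acceptance band as a fraction of eps
#'   (default 0.05).
#' @param window Running-mean window, ms (default 10000).
#' @return data.frame \code{(population, eps, converged, t_converge_ms,
#'   final_mean)} where \code{final_mean} is the raw trace mean over its
#'   final smoothing window.
#' @export
calcium_summary <- function(calcium, eps, band = 0.05, window = 10000) {
  stopifnot(all(c("time_ms", "population", "ca_mean") %in% names(calcium)))
  pops <- unique(calcium$population)
  if (is.null(names(eps))) {
    if (length(eps) == 1L) eps <- stats::setNames(rep(eps, length(pops)), pops)
    else stop("'eps' must be named by population")
  }
  out <- lapply(pops, function(p) {
    tr <- calcium[calcium$population == p, ]
    tr <- tr[order(tr$time_ms), ]
    dtv <- diff(tr$time_ms)
    if (length(dtv) && max(abs(dtv - dtv[1])) > 1e-6)
      stop("calcium trace must be regularly sampled")
    step <- if (length(dtv)) dtv[1] else window
    w <- max(1L, min(nrow(tr), as.integer(round(window / step))))
    cs <- cumsum(tr$ca_mean)
    run <- (cs - c(rep(0, w), utils::head(cs, -w))) /
      pmin(seq_along(cs), w)
    e <- eps[[p]]
    inside <- abs(run - e) <= band * e
    # first index from which the running mean never leaves the band
    ok <- rev(cumprod(rev(inside))) == 1
    t_conv <- if (any(ok)) tr$time_ms[which(ok)[1]] else NA_real_
    data.frame(population = p, eps = e, converged = any(ok),
               t_converge_ms = t_conv,
               final_mean = mean(utils::tail(tr$ca_mean, w)))
  })
  do.call(rbind, out)
}

#' Write and read recorder output as CSV
#'
#' Plain-CSV writers/readers for the three recorded streams: spike rasters
#' \code{(time_ms, neuron_id)}, calcium samples
#' \code{(time_ms, population, ca)} and connectivity snapshots (square
#' population-pair count matrices with a leading source-population column).
#' Writers and readers round-trip exactly.
#'
#' @param x The object to write (data.frame or matrix, see details).
#' @param path File path.
#' @return Readers return the reconstructed object; writers return
#'   \code{path} invisibly.
#' @name recorder_io
NULL

#' @rdname recorder_io
#' @param append Append to an existing raster file instead of overwriting
#'   (the header is written only once), so successive simulation chunks can
#'   stream into one file.
#' @export
write_spikes <- function(x, path, append = FALSE) {
  stopifnot(all(c("time_ms", "neuron") %in% names(x)))
  new_file <- !(append && file.exists(path))
  suppressWarnings(
    utils::write.table(x[, c("time_ms", "neuron")], path, sep = ",",
                       row.names = FALSE, col.names = new_file,
                       append = !new_file))
  invisible(path)
}

#' @rdname recorder_io
#' @export
read_spikes <- function(path) {
  utils::read.csv(path, colClasses = c("numeric", "integer"))
}

#' @rdname recorder_io
#' @export
write_calcium <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname recorder_io
#' @export
read_calcium <- function(path) {
  out <- utils::read.csv(path)
  out$population <- as.character(out$population)
  out
}

#' @rdname recorder_io
#' @export
write_connectivity <- function(x, path) {
  m <- as.matrix(x)
  df <- data.frame(source = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname recorder_io
#' @export
read_connectivity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- if (all(m == round(m))) "integer" else "double"
  m
}
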