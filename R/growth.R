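#' Homeostatic growth curve for one synaptic element type
#'
#' A growth curve maps the neuron's calcium concentration to the rate dz/dt
#' (elements/ms) at which synaptic elements of one type are created or
#' deleted.  Two shapes are supported:
#' \describe{
#'   \item{linear}{\eqn{dz/dt = \nu (1 - Ca/\epsilon)}: positive below the
#'     setpoint \eqn{\epsilon}, negative above it.}
#'   \item{gaussian}{\eqn{dz/dt = \nu (2 e^{-((Ca-\xi)/\zeta)^2} - 1)} with
#'     \eqn{\xi = (\eta+\epsilon)/2} and \eqn{\zeta = (\epsilon-\eta)/(2\sqrt{\ln 2})}.
#'     The rate is zero at both \eqn{\eta} (the minimum calcium needed to form
#'     elements at all) and the setpoint \eqn{\epsilon}, peaks at \eqn{\nu} at
#'     the midpoint \eqn{\xi}, and tends to \eqn{-\nu} far outside
#'     \eqn{[\eta,\epsilon]}.}
#' }
#' The squared exponent is required for the stated zero crossings at
#' \eqn{\eta} and \eqn{\epsilon} together with the \eqn{\sqrt{\ln 2}} scale
#' factor; \eqn{\xi} and \eqn{\zeta} are always derived from \code{eta} and
#' \code{eps}, never stored independently.
#'
#' @param kind "linear" or "gaussian".
#' @param nu Growth rate, elements/ms; the peak speed of element creation or
#'   deletion. Must be positive.
#' @param eps Target (setpoint) calcium concentration, Ca units.
#' @param eta Minimum calcium to form elements (gaussian only), Ca units;
#'   must be strictly below \code{eps}.
#' @param continuous If \code{FALSE} (default, mirroring the usual config
#'   surface) reported element counts are truncated integers; the internal z
#'   variable is always continuous.
#' @return An object of class \code{growth_curve}.
#' @examples
#' gc <- growth_curve("gaussian", nu = 1e-4, eps = 0.05, eta = 0)
#' growth_rate(gc, c(0, 0.025, 0.05, 1))  # 0, peak nu, 0, ~ -nu
#' @export
growth_curve <- function(kind = c("gaussian", "linear"), nu, eps, eta = 0,
                         continuous = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(nu), length(nu) == 1L, nu > 0,
            is.numeric(eps), length(eps) == 1L, eps > 0)
  if (kind == "gaussian") {
    stopifnot(is.numeric(eta), length(eta) == 1L)
    if (eta >= eps) stop("gaussian growth curve requires eta < eps")
  }
  structure(list(kind = kind, nu = nu, eps = eps,
                 eta = if (kind == "gaussian") eta else NA_real_,
                 continuous = isTRUE(continuous)),
            class = "growth_curve")
}

#' @rdname growth_curve
#' @param curve A \code{growth_curve}.
#' @param ca Calcium concentration(s), Ca units (non-negative); vectorized.
#' @return \code{growth_rate}: dz/dt in elements/ms, same length as \code{ca}.
#' @export
growth_rate <- function(curve, ca) {
  stopifnot(inherits(curve, "growth_curve"), all(ca >= 0))
  if (curve$kind == "linear") {
    curve$nu * (1 - ca / curve$eps)
  } else {
    xi <- (curve$eta + curve$eps) / 2
    zeta <- (curve$eps - curve$eta) / (2 * sqrt(log(2)))
    curve$nu * (2 * exp(-((ca - xi) / zeta)^2) - 1)
  }
}

#' Per-neuron pool of synaptic elements of one type
#'
#' Tracks the continuous element variable \code{z}, which may transiently go
#' negative (a deficit that must be regrown before elements reappear), and the
#' integer number of elements currently bound in synapses. The number of
#' vacant (formed but unbound) elements is \code{floor(max(z,0)) - connected},
#' clamped at zero.
#'
#' @param type Element-type label, e.g. "Axon_ex", "Den_ex", "Den_in".
#' @param z Continuous element count.
#' @param connected Integer count of elements bound in synapses.
#' @return An object of class \code{element_pool}.
#' @export
element_pool <- function(type, z = 0, connected = 0L) {
  stopifnot(is.character(type), length(type) == 1L,
            is.numeric(z), length(z) == 1L,
            is.numeric(connected), length(connected) == 1L, connected >= 0)
  structure(list(type = type, z = z, connected = as.integer(connected)),
            class = "element_pool")
}

#' @rdname element_pool
#' @param pool An \code{element_pool}.
#' @return \code{vacant_count}: integer number of vacant elements.
#' @export
vacant_count <- function(pool) {
  stopifnot(inherits(pool, "element_pool"))
  max(0L, as.integer(floor(max(pool$z, 0))) - pool$connected)
}

#' Integrate the element variable over one structural interval
#'
#' Advances \code{z} under the growth curve, using the calcium value at the
#' start of the interval, and reports the discrete consequences: how many new
#' vacant elements appeared (the rounded-down z crossed an integer upward) and
#' how many connected elements must be released because the available count
#' fell below the number of bound elements.
#'
#' The linear curve is integrated exactly under pure calcium decay over the
#' interval, \eqn{Ca(t) = Ca_0 e^{-t/\tau}}:
#' \deqn{\Delta z = \nu\,dt - (\nu/\epsilon)\, Ca_0\, \tau (1 - e^{-dt/\tau}).}
#' The gaussian curve takes a single forward-Euler step,
#' \eqn{\Delta z = dz/dt(Ca_0)\, dt}. Spikes that occur inside the interval
#' are absorbed into the next interval's starting calcium.
#'
#' @param pool An \code{\link{element_pool}}.
#' @param curve A \code{\link{growth_curve}}.
#' @param ca_start Calcium at the start of the interval, Ca units.
#' @param dt Structural update interval, ms (> 0).
#' @param cal A \code{\link{calcium_params}} (supplies the decay constant for
#'   the exact linear integral).
#' @return A list with elements \code{pool} (updated), \code{n_new_vacant}
#'   and \code{n_deleted}.
#' @export
integrate_elements <- function(pool, curve, ca_start, dt, cal) {
  stopifnot(inherits(pool, "element_pool"), inherits(curve, "growth_curve"),
            inherits(cal, "calcium_params"), dt > 0, ca_start >= 0)
  dz <- element_delta(curve$kind, curve$nu, curve$eps, curve$eta,
                      ca_start, dt, cal$tau)
  f_old <- floor(max(pool$z, 0))
  pool$z <- pool$z + dz
  f_new <- floor(max(pool$z, 0))
  n_new_vacant <- max(0L, as.integer(f_new - f_old))
  n_deleted <- max(0L, pool$connected - as.integer(f_new))
  list(pool = pool, n_new_vacant = n_new_vacant, n_deleted = n_deleted)
}

# Vectorized core of integrate_elements, shared with the simulation engine.
# kind: "linear"/"gaussian" (recycled); returns delta z.
element_delta <- function(kind, nu, eps, eta, ca_start, dt, tau) {
  xi <- (eta + eps) / 2
  zeta <- (eps - eta) / (2 * sqrt(log(2)))
  lin <- nu * dt - (nu / eps) * ca_start * tau * (1 - exp(-dt / tau))
  gau <- nu * (2 * exp(-((ca_start - xi) / zeta)^2) - 1) * dt
  ifelse(kind == "linear", lin, gau)
}

#' Prune vacant synaptic elements
#'
#' Reduces the continuous element variable by a fraction of the current vacant
#' count, modelling the decay of unused contact sites between connectivity
#' updates. Connected elements are never touched. When
#' \code{fraction * vacant} is non-integer, z is reduced fractionally.
#'
#' @param pool An \code{\link{element_pool}}.
#' @param fraction Fraction of vacant elements removed per call, in [0, 1].
#' @return The updated \code{element_pool}.
#' @export
prune_vacant <- function(pool, fraction) {
  stopifnot(inherits(pool, "element_pool"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must be a single number in [0, 1]")
  pool$z <- pool$z - fraction * vacant_count(pool)
  pool
}

#' Reported element count of a pool
#'
#' Honors the curve's \code{continuous} flag: continuous pools report z
#' itself, discrete pools report the truncated integer count.
#'
#' @inheritParams integrate_elements
#' @return Numeric element count.
#' @export
element_count <- function(pool, curve) {
  stopifnot(inherits(pool, "element_pool"), inherits(curve, "growth_curve"))
  if (curve$continuous) pool$z else floor(max(pool$z, 0))
}
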