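#' Exponential escape rate (conditional intensity)
#'
#' The hazard rate of a GIF neuron with membrane potential `u` and total
#' dynamic threshold `theta_total`:
#' \deqn{\lambda = c\, e^{(u - \vartheta)/\Delta_u}.}
#' At `u == theta_total` the rate equals `c` (the escape rate at
#' threshold); the rate increases by a factor `e` for every `delta_u`
#' millivolts of additional depolarization. `theta_total = Inf` encodes
#' absolute refractoriness and yields a rate of exactly 0. The exponent
#' is clamped at +20 before exponentiation so that strongly suprathreshold
#' excursions produce a large but finite rate; the firing probability per
#' step, \eqn{1 - e^{-\bar\lambda \Delta t}}, is bounded regardless.
#'
#' @param u membrane potential in mV (vectorised).
#' @param theta_total total threshold \eqn{\vartheta} in mV (`Inf` during
#'   absolute refractoriness).
#' @param c escape rate at threshold in 1/s (>= 0).
#' @param delta_u threshold softness in mV (> 0).
#' @return hazard rate(s) in 1/s.
#' @examples
#' escape_rate(15, 15, c = 10, delta_u = 2)   # exactly c
#' escape_rate(17, 15, c = 10, delta_u = 2)   # c * e
#' @export
escape_rate <- function(u, theta_total, c = 10, delta_u = 2) {
  if (!is.finite(delta_u) || delta_u <= 0) stop("delta_u must be > 0")
  if (any(!is.finite(u))) stop("non-finite membrane potential u")
  if (any(c < 0)) stop("c must be >= 0")
  x <- (u - theta_total) / delta_u
  # theta_total = Inf => x = -Inf => rate 0 (absolute refractoriness)
  x[is.nan(x)] <- -Inf
  c * exp(pmin(x, ESCAPE_EXPONENT_CAP))
}

# Clamp for the escape-rate exponent; shared with the C++ integrators.
ESCAPE_EXPONENT_CAP <- 20
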