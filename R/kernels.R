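#' Spike-triggered threshold kernel as a sum of exponentials
#'
#' Constructs the spike-triggered kernel
#' \deqn{\theta(t) = \sum_\ell (J_\ell/\tau_\ell)\, e^{-t/\tau_\ell}, \quad t \ge t_{ref},}
#' with \eqn{\theta(t) = \infty} during the absolute refractory period
#' \eqn{0 < t < t_{ref}} (encoded as a sentinel that forces zero firing
#' probability downstream) and \eqn{\theta(t) = 0} for \eqn{t \le 0}.
#' Each spike of a neuron adds one copy of this kernel to its dynamic
#' threshold, producing refractoriness, spike-frequency adaptation
#' (positive components) or facilitation (negative components).
#' The same structure represents the spike-after-potential kernel
#' \eqn{\eta(t)} of the GLM/spike-response model variant.
#'
#' @param J numeric vector of component strengths \eqn{J_\ell} in mV s
#'   (may be empty for a kernel that is purely absolute refractoriness).
#' @param tau numeric vector of component time scales \eqn{\tau_\ell} in s.
#' @param t_ref absolute refractory period in s (must be > 0).
#' @return An object of class `adaptation_kernel`.
#' @examples
#' k <- adaptation_kernel(J = c(1.5, 1.5), tau = c(0.01, 1), t_ref = 0.004)
#' theta_kernel_eval(k, c(0.002, 0.05, 1))
#' @export
adaptation_kernel <- function(J = numeric(0), tau = numeric(0), t_ref = 0.004) {
  J <- as.numeric(J)
  tau <- as.numeric(tau)
  if (length(J) != length(tau)) {
    stop("J and tau must have the same length")
  }
  if (length(tau) && any(tau <= 0)) stop("all kernel time scales tau must be > 0")
  if (!is.finite(t_ref) || t_ref <= 0) stop("t_ref must be a positive number")
  structure(list(J = J, tau = tau, t_ref = t_ref), class = "adaptation_kernel")
}

#' @export
print.adaptation_kernel <- function(x, ...) {
  cat("<adaptation_kernel> t_ref =", x$t_ref, "s;",
      length(x$J), "exponential component(s)\n")
  if (length(x$J)) {
    print(data.frame(J_mVs = x$J, tau_s = x$tau))
  }
  invisible(x)
}

n_components <- function(kernel) length(kernel$J)

is_empty_kernel <- function(kernel) {
  is.null(kernel) || length(kernel$J) == 0L
}

#' Evaluate a spike-triggered kernel
#'
#' Returns \eqn{\theta(t)} in mV: 0 for `t <= 0`, `Inf` for
#' `0 < t < t_ref` (absolute refractoriness) and the exponential sum for
#' `t >= t_ref`.
#'
#' @param kernel an [adaptation_kernel()].
#' @param t numeric vector of time lags since the spike, in s.
#' @return numeric vector of kernel values in mV (`Inf` marks absolute
#'   refractoriness).
#' @export
theta_kernel_eval <- function(kernel, t) {
  stopifnot(inherits(kernel, "adaptation_kernel"))
  out <- numeric(length(t))
  refr <- t > 0 & t < kernel$t_ref
  out[refr] <- Inf
  tail <- t >= kernel$t_ref
  if (any(tail) && length(kernel$J)) {
    tt <- t[tail]
    acc <- 0
    for (l in seq_along(kernel$J)) {
      acc <- acc + (kernel$J[l] / kernel$tau[l]) * exp(-tt / kernel$tau[l])
    }
    out[tail] <- acc
  }
  out
}

#' Quasi-renewal kernel
#'
#' The quasi-renewal approximation averages the threshold contributions of
#' all spikes before the last one, assuming they occurred as an
#' inhomogeneous Poisson process with rate given by the population
#' activity. The averaged kernel is
#' \deqn{\tilde\theta(t) = \Delta_u \left[1 - e^{-\theta(t)/\Delta_u}\right].}
#' It satisfies \eqn{\tilde\theta(t) \le \min(\theta(t), \Delta_u)} for
#' \eqn{\theta \ge 0} and saturates at \eqn{\Delta_u} where \eqn{\theta}
#' is large (e.g. during absolute refractoriness).
#'
#' @param kernel an [adaptation_kernel()].
#' @param t numeric vector of positive time lags in s.
#' @param delta_u threshold softness \eqn{\Delta_u} in mV (> 0).
#' @return numeric vector of \eqn{\tilde\theta(t)} in mV.
#' @export
quasi_renewal_kernel <- function(kernel, t, delta_u) {
  if (!is.finite(delta_u) || delta_u <= 0) stop("delta_u must be > 0")
  th <- theta_kernel_eval(kernel, t)
  delta_u * (1 - exp(-th / delta_u))
}

# Upper envelope sum_l |J_l/tau_l| exp(-t/tau_l); monotone decreasing bound
# on |theta(t)| used when choosing the explicit-history length.
theta_kernel_envelope <- function(kernel, t) {
  if (!length(kernel$J)) return(rep(0, length(t)))
  acc <- numeric(length(t))
  for (l in seq_along(kernel$J)) {
    acc <- acc + abs(kernel$J[l] / kernel$tau[l]) * exp(-t / kernel$tau[l])
  }
  acc
}
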