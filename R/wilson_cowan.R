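#' Exact expected activity of an absolute-refractory Poisson population
#'
#' For a (self-coupled) population whose hazard is
#' \eqn{\lambda(t|\hat t) = f(h(t))\,\Theta(t - \hat t - t_{ref})} - i.e.
#' neurons that are Poisson once outside the absolute refractory period,
#' with no voltage reset and no relative refractoriness - the mesoscopic
#' population equation closes exactly:
#' \deqn{\bar A(t) = f(h(t)) \left[1 - \int_{t - t_{ref}}^{t} A_N(\hat t)
#'   \, d\hat t \right],}
#' the product of the free rate and the fraction of non-refractory
#' neurons. This function recomputes \eqn{\bar A(t)} directly from this
#' relation, given the realized activity history of a trace, using its
#' own free-potential recursion; it shares no state with the general
#' integrator and serves as an independent check of the latter (which
#' must reproduce it to machine precision for such populations, i.e. for
#' the GLM variant with empty kernels).
#'
#' @param spec a single-population [network_spec()] whose population has
#'   `model_variant = "GLM"` and empty `theta`/`eta` kernels.
#' @param trace an [activity_trace()] produced from `spec` (the realized
#'   history \eqn{A_N} enters the right-hand side).
#' @param settings the [sim_settings()] used for `trace` (for `dt`; the
#'   trace must have been recorded without warmup).
#' @details At finite step size the integrated hazard of each group of
#' neurons is averaged trapezoidally over the step. The cohort whose
#' absolute refractory period ends exactly at the current bin boundary
#' therefore carries half a step of hazard (its intensity is 0 at the
#' start of the step and \eqn{f(h)} at its end); older cohorts and free
#' neurons carry the full trapezoid. This is the direct discrete
#' transcription of the closed equation above.
#'
#' @return numeric vector of expected activities \eqn{\bar A(t_l)} in
#'   1/s, one per bin of `trace`.
#' @export
wilson_cowan_expected <- function(spec, trace, settings) {
  stopifnot(inherits(spec, "network_spec"), n_populations(spec) == 1L)
  pop <- spec$populations[[1]]
  if (pop$model_variant != "GLM" || n_components(pop$theta) ||
      !is_empty_kernel(pop$eta)) {
    stop("the exact reduction requires a GLM population with empty kernels")
  }
  dt <- settings$dt
  n <- nrow(trace$counts)
  N <- pop$N
  k_ref <- max(1L, as.integer(round(pop$t_ref / dt)))
  em <- exp(-dt / pop$tau_m)
  es <- exp(-dt / spec$tau_s[1])
  coefY <- if (abs(spec$tau_s[1] - pop$tau_m) < 1e-9) dt * em else {
    pop$tau_m * spec$tau_s[1] / (spec$tau_s[1] - pop$tau_m) * (es - em)
  }
  coefA <- pop$tau_m * (1 - em)
  J <- spec$p[1, 1] * N * spec$w[1, 1]
  dstep <- max(1L, as.integer(round(spec$delay[1, 1] / dt)))
  stim <- eval_stimulus(spec$stimulus[[1]], (0:(n - 1)) * dt)
  # activity history; bin -1 holds the synchronization pulse (if any)
  sync <- !identical(settings$init, "free")
  A <- c(if (sync) 1 / dt else 0, trace$counts[, 1] / (N * dt))
  dn <- c(if (sync) N else 0, trace$counts[, 1])
  h <- pop$u_rest
  y <- 0
  f <- function(h) pop$c * exp(pmin((h - pop$u_th) / pop$delta_u, 20))
  lam <- f(h)
  out <- numeric(n)
  for (l in 0:(n - 1)) {
    idx <- l - dstep + 2L
    Ad <- if (idx >= 1L) A[idx] else 0
    h_tot <- stim[l + 1L] * (1 - em)
    if (J != 0) h_tot <- h_tot + J * (Ad * coefA + (y - Ad) * coefY)
    y <- Ad + (y - Ad) * es
    h_new <- pop$u_rest + (h - pop$u_rest) * em + h_tot
    lam_new <- f(h_new)
    P_full <- 1 - exp(-0.5 * (lam + lam_new) * dt)
    P_half <- 1 - exp(-0.5 * lam_new * dt)
    # spikes in the last k_ref bins are refractory; the oldest of them
    # (the cohort exiting refractoriness during this step) fires with the
    # half-step hazard
    kk <- (l - k_ref):(l - 1)
    n_ref <- sum(dn[kk[kk >= -1L] + 2L])
    k_bnd <- l - k_ref
    dn_bnd <- if (k_bnd >= -1L) dn[k_bnd + 2L] else 0
    dn_bar <- min(max(P_full * (N - n_ref) + P_half * dn_bnd, 0), N)
    out[l + 1L] <- dn_bar / (N * dt)
    h <- h_new
    lam <- lam_new
  }
  out
}
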