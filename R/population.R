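#' Parameters of one homogeneous neuron population
#'
#' Bundles the single-neuron and noise parameters shared by all `N`
#' neurons of a population of generalized integrate-and-fire (GIF)
#' neurons with escape noise, or of the GLM/spike-response variant.
#'
#' @param N number of neurons (>= 1).
#' @param tau_m membrane time constant in s.
#' @param t_ref absolute refractory period in s.
#' @param u_th baseline threshold in mV.
#' @param u_r reset potential in mV (GIF variant).
#' @param u_rest resting potential in mV.
#' @param c escape rate at threshold in 1/s.
#' @param delta_u threshold softness in mV.
#' @param theta spike-triggered threshold kernel ([adaptation_kernel()]);
#'   defaults to an empty kernel (pure absolute refractoriness) with
#'   `t_ref` as its dead time.
#' @param eta spike-after-potential kernel for the GLM variant, or `NULL`.
#' @param model_variant `"GIF"` (voltage reset and clamp) or `"GLM"`
#'   (no reset; spike history enters the potential via `eta`).
#' @param name optional population label.
#' @return An object of class `population_params`.
#' @examples
#' # Table-default LIF population
#' population_params(N = 500)
#' @export
population_params <- function(N,
                              tau_m = 0.02,
                              t_ref = 0.004,
                              u_th = 15,
                              u_r = 0,
                              u_rest = 0,
                              c = 10,
                              delta_u = 2,
                              theta = NULL,
                              eta = NULL,
                              model_variant = c("GIF", "GLM"),
                              name = NULL) {
  model_variant <- match.arg(model_variant)
  if (!is.numeric(N) || N < 1) stop("N must be >= 1")
  if (tau_m <= 0) stop("tau_m must be > 0")
  if (t_ref <= 0) stop("t_ref must be > 0")
  if (delta_u <= 0) stop("delta_u must be > 0")
  if (c < 0) stop("c must be >= 0")
  if (is.null(theta)) theta <- adaptation_kernel(t_ref = t_ref)
  stopifnot(inherits(theta, "adaptation_kernel"))
  if (!isTRUE(all.equal(theta$t_ref, t_ref))) {
    stop("theta kernel t_ref must equal the population t_ref")
  }
  if (model_variant == "GIF" && !is_empty_kernel(eta)) {
    stop("GIF variant uses the voltage reset; eta must be empty")
  }
  if (!is.null(eta)) stopifnot(inherits(eta, "adaptation_kernel"))
  structure(list(N = as.integer(round(N)), tau_m = tau_m, t_ref = t_ref,
                 u_th = u_th, u_r = u_r, u_rest = u_rest, c = c,
                 delta_u = delta_u, theta = theta, eta = eta,
                 model_variant = model_variant, name = name),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(
    "<population_params>%s %s, N = %d, tau_m = %g s, t_ref = %g s,\n  u_th = %g mV, u_r = %g mV, u_rest = %g mV, c = %g 1/s, delta_u = %g mV,\n  %d threshold kernel component(s)\n",
    if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
    x$model_variant, x$N, x$tau_m, x$t_ref, x$u_th, x$u_r, x$u_rest,
    x$c, x$delta_u, n_components(x$theta)))
  invisible(x)
}

#' Piecewise-constant step stimulus
#'
#' Describes the external drive \eqn{RI_{ext}(t)} of one population as a
#' set of rectangular steps; the total drive is
#' \eqn{\mu(t) = u_{rest} + RI_{ext}(t)}. Step windows are closed on the
#' left and open on the right.
#'
#' @param t_on,t_off numeric vectors of step onsets/offsets in s.
#' @param amplitude step amplitudes in mV.
#' @return A data frame with columns `t_on`, `t_off`, `amplitude`.
#' @export
step_stimulus <- function(t_on = numeric(0), t_off = numeric(0),
                          amplitude = numeric(0)) {
  stopifnot(length(t_on) == length(t_off),
            length(t_on) == length(amplitude))
  if (length(t_on) && any(t_off <= t_on)) stop("t_off must exceed t_on")
  data.frame(t_on = as.numeric(t_on), t_off = as.numeric(t_off),
             amplitude = as.numeric(amplitude))
}

eval_stimulus <- function(stim, times) {
  out <- numeric(length(times))
  if (is.null(stim) || nrow(stim) == 0L) return(out)
  for (i in seq_len(nrow(stim))) {
    out <- out + stim$amplitude[i] *
      (times >= stim$t_on[i] & times < stim$t_off[i])
  }
  out
}

#' Network of interacting populations
#'
#' Combines `M` populations with their connectivity: connection
#' probabilities `p` (row = target population, column = source), synaptic
#' weights `w` in mV, transmission delays in s, per-source synaptic decay
#' time constants `tau_s` in s, and per-population step stimuli. The
#' effective mesoscopic coupling is \eqn{J^{\alpha\beta} =
#' p^{\alpha\beta} N^\beta w^{\alpha\beta}}.
#'
#' @param populations list of [population_params()] objects.
#' @param p M x M matrix of connection probabilities in `[0, 1]`.
#' @param w M x M matrix of synaptic weights in mV.
#' @param delay M x M matrix of transmission delays in s (> 0), or a
#'   scalar applied to all pairs.
#' @param tau_s length-M vector of synaptic time constants of the
#'   *source* populations, in s.
#' @param stimulus list of length M of [step_stimulus()] data frames
#'   (or `NULL` entries for unstimulated populations).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(populations, p = NULL, w = NULL, delay = 0.001,
                         tau_s = NULL, stimulus = NULL) {
  if (inherits(populations, "population_params")) populations <- list(populations)
  M <- length(populations)
  stopifnot(M >= 1, all(vapply(populations, inherits, TRUE, "population_params")))
  if (is.null(p)) p <- matrix(0, M, M)
  if (is.null(w)) w <- matrix(0, M, M)
  if (length(delay) == 1L) delay <- matrix(delay, M, M)
  if (is.null(tau_s)) tau_s <- rep(0.003, M)
  p <- as.matrix(p); w <- as.matrix(w); delay <- as.matrix(delay)
  stopifnot(all(dim(p) == M), all(dim(w) == M), all(dim(delay) == M),
            length(tau_s) == M)
  if (any(p < 0 | p > 1)) stop("connection probabilities must lie in [0, 1]")
  if (any(delay <= 0)) stop("all transmission delays must be > 0")
  if (any(tau_s <= 0)) stop("all tau_s must be > 0")
  N <- vapply(populations, function(q) q$N, 0L)
  if (any(!is.finite(p * matrix(N, M, M, byrow = TRUE) * w))) {
    stop("effective coupling J = p * N * w must be finite")
  }
  if (is.null(stimulus)) stimulus <- vector("list", M)
  stopifnot(length(stimulus) == M)
  nm <- vapply(populations, function(q) q$name %||% "", "")
  if (all(nzchar(nm))) {
    dimnames(p) <- dimnames(w) <- dimnames(delay) <- list(nm, nm)
  }
  structure(list(populations = populations, p = p, w = w, delay = delay,
                 tau_s = as.numeric(tau_s), stimulus = stimulus),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  N <- vapply(x$populations, function(q) q$N, 0L)
  cat(sprintf("<network_spec> %d population(s), N = [%s]\n",
              length(x$populations), paste(N, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_populations <- function(spec) length(spec$populations)

pop_sizes <- function(spec) vapply(spec$populations, function(q) q$N, 0L)

#' Simulation settings
#'
#' @param dt integration time step in s. Must not exceed any absolute
#'   refractory period or any transmission delay.
#' @param duration simulated time in s.
#' @param seed RNG seed (integer).
#' @param history_T explicit-history length in s: `"auto"` (computed per
#'   population by [choose_history_length()]), a scalar, or a vector with
#'   one entry per population.
#' @param sampling how the spike count is drawn from the expected count:
#'   `"binomial"` (default), `"poisson"` (truncated at N), `"gaussian"`
#'   (rounded and clipped), or `"expected"` (deterministic, the
#'   infinite-N proxy where \eqn{\Delta n = \bar{\Delta n}}).
#' @param record_expected store the expected activity \eqn{\bar A(t)}
#'   alongside the sampled one.
#' @param record_raster store the (time, population, neuron) spike list
#'   in microscopic simulations.
#' @param init initial condition: `"synchronized"` (all neurons fire at
#'   \eqn{t = -\Delta t}; the classic sharp initialization), `"free"`
#'   (all neurons start without spike history, i.e. in the free pool at
#'   rest), or `"stationary"` (mesoscopic runs only: start in the
#'   self-consistent asynchronous stationary state computed by
#'   [stationary_rates()]). The synchronized start is convenient
#'   analytically, but in strongly coupled networks it can fall into an
#'   artificial self-sustaining cluster state in which whole cohorts
#'   re-fire the moment they leave the refractory period; use the
#'   stationary start to measure spontaneous activity there.
#' @param warmup length in s of a deterministic burn-in (sampling
#'   replaced by the expected count) run before the stochastic part;
#'   useful to skip the synchronization transient when measuring
#'   stationary statistics. The recorded trace covers only the
#'   stochastic part.
#' @param tol_theta tolerance used by `history_T = "auto"`: the explicit
#'   history ends where \eqn{|\theta(t)| \le} `tol_theta` \eqn{\cdot \Delta_u}.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(dt = 2e-4, duration = 1, seed = 1L,
                         history_T = "auto",
                         sampling = c("binomial", "poisson", "gaussian",
                                      "expected"),
                         init = c("synchronized", "free", "stationary"),
                         record_expected = FALSE,
                         record_raster = FALSE,
                         warmup = 0,
                         tol_theta = 0.01) {
  sampling <- match.arg(sampling)
  init <- match.arg(init)
  if (dt <= 0) stop("dt must be > 0")
  if (duration < 0) stop("duration must be >= 0")
  if (warmup < 0) stop("warmup must be >= 0")
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 history_T = history_T, sampling = sampling, init = init,
                 record_expected = isTRUE(record_expected),
                 record_raster = isTRUE(record_raster),
                 warmup = warmup, tol_theta = tol_theta),
            class = "sim_settings")
}

#' Length of the explicit refractory history
#'
#' Chooses the shortest history `T` over which the dependence of the
#' hazard on the last spike time must be tracked explicitly. Neurons with
#' older last spikes are treated as "free". `T` must cover both the
#' relative refractory period, `T >= n_rel * max(t_ref, tau_m)`, and the
#' range where the spike-triggered kernel is non-negligible,
#' \eqn{|\theta(t)| \le} `tol_theta` \eqn{\cdot \Delta_u} for all
#' `t > T`. Note that `T` does not need to reach the longest kernel time
#' scale: a slow component of small amplitude `J/tau` is absorbed into
#' the free-neuron threshold.
#'
#' @param pop a [population_params()] object.
#' @param tol_theta dimensionless tolerance in (0, 1), default 0.01.
#' @param n_rel multiple of `max(t_ref, tau_m)` that the history must
#'   cover, default 5.
#' @param dt optional grid step in s; if given, `T` is rounded up to a
#'   multiple of `dt`.
#' @return history length `T` in s.
#' @examples
#' choose_history_length(population_params(N = 100))  # 5 * tau_m = 0.1 s
#' @export
choose_history_length <- function(pop, tol_theta = 0.01, n_rel = 5,
                                  dt = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (tol_theta <= 0 || tol_theta >= 1) stop("tol_theta must be in (0, 1)")
  T0 <- n_rel * max(pop$t_ref, pop$tau_m)
  kern <- pop$theta
  if (!is_empty_kernel(pop$eta)) {
    # GLM: the spike-after-potential acts like a (sign-flipped) threshold
    # kernel for the purpose of history truncation.
    kern <- adaptation_kernel(J = c(kern$J, -pop$eta$J),
                              tau = c(kern$tau, pop$eta$tau),
                              t_ref = kern$t_ref)
  }
  T_out <- T0
  if (!is_empty_kernel(kern)) {
    bound <- tol_theta * pop$delta_u
    cap <- 100 * max(kern$tau)
    if (theta_kernel_envelope(kern, T0) > bound) {
      if (theta_kernel_envelope(kern, cap) > bound) {
        stop(sprintf(
          "spike-triggered kernel does not decay below %.3g mV within the cap T = %.3g s",
          bound, cap))
      }
      T_out <- stats::uniroot(
        function(t) theta_kernel_envelope(kern, t) - bound,
        lower = T0, upper = cap, tol = 1e-12)$root
    }
  }
  if (!is.null(dt)) T_out <- ceiling(T_out / dt - 1e-9) * dt
  T_out
}

resolve_history <- function(spec, settings) {
  M <- n_populations(spec)
  hT <- settings$history_T
  if (identical(hT, "auto")) {
    hT <- vapply(spec$populations, choose_history_length, 0,
                 tol_theta = settings$tol_theta, dt = settings$dt)
  } else {
    hT <- rep_len(as.numeric(hT), M)
    hT <- ceiling(hT / settings$dt - 1e-9) * settings$dt
  }
  hT
}

#' Validate an integration time step against a network
#'
#' Hard conditions: the step must not exceed any absolute refractory
#' period (so that each neuron fires at most once per step) and must not
#' exceed any transmission delay (so that within one step populations can
#' be updated independently). A third, soft condition requires the
#' trapezoidal approximation of the integrated hazard to be accurate; it
#' depends on the realized trajectory and is therefore probed on a short
#' deterministic mesoscopic run of the free-neuron dynamics: the local
#' relative error estimate
#' \eqn{[(d')^2 + \Delta_u |d''|]\,\Delta t^2 / (12 \Delta_u^2)} with
#' \eqn{d = h - \vartheta_{free}} should be small.
#'
#' @param spec a [network_spec()].
#' @param dt candidate time step in s.
#' @param probe logical; run the trapezoid-condition probe (default TRUE).
#' @param probe_duration length of the probe trajectory in s.
#' @return (invisibly) a list with elements `pass_t_ref`, `pass_delay`,
#'   `trapezoid_ok` and `trapezoid_ratio` (max local relative-error
#'   estimate; `NA` if not probed). Hard failures raise an error; a
#'   trapezoid violation raises a warning.
#' @export
validate_dt <- function(spec, dt, probe = TRUE, probe_duration = 0.25) {
  stopifnot(inherits(spec, "network_spec"))
  if (dt <= 0) stop("dt must be > 0")
  t_refs <- vapply(spec$populations, function(q) q$t_ref, 0)
  pass_t_ref <- dt <= min(t_refs) + 1e-12
  pass_delay <- dt <= min(spec$delay) + 1e-12
  if (!pass_t_ref) {
    stop(sprintf("dt = %g s exceeds the smallest absolute refractory period (%g s)",
                 dt, min(t_refs)))
  }
  if (!pass_delay) {
    stop(sprintf("dt = %g s exceeds the smallest transmission delay (%g s)",
                 dt, min(spec$delay)))
  }
  ratio <- NA_real_
  if (probe) {
    st <- sim_settings(dt = dt, duration = probe_duration, seed = 1L,
                       sampling = "expected")
    tr <- run_meso(spec, st, validate = FALSE, record_free_potential = TRUE)
    ratio <- 0
    for (a in seq_len(n_populations(spec))) {
      d <- tr$free_potential[, a] - tr$free_threshold[, a]
      if (length(d) >= 3) {
        d1 <- diff(d) / dt
        d2 <- diff(d, differences = 2) / dt^2
        du <- spec$populations[[a]]$delta_u
        loc <- (d1[-1]^2 + du * abs(d2)) * dt^2 / (12 * du^2)
        ratio <- max(ratio, loc)
      }
    }
    if (ratio > 0.1) {
      warning(sprintf(
        "trapezoidal-hazard condition violated on probe trajectory (max local error ratio %.3g); consider a smaller dt",
        ratio))
    }
  }
  invisible(list(pass_t_ref = pass_t_ref, pass_delay = pass_delay,
                 trapezoid_ok = is.na(ratio) || ratio <= 0.1,
                 trapezoid_ratio = ratio))
}
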