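#' @useDynLib mesopop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sampling_mode_code <- function(sampling) {
  match(sampling, c("binomial", "poisson", "gaussian", "expected")) - 1L
}

# Precompute, for each population, the kernel tables and decay factors the
# integrators need: theta(lag*dt), quasi-renewal kernel/N, eta(lag*dt) for
# lags 0..K+1, adaptation decays, membrane/synaptic one-step coefficients,
# effective couplings J = p*N*w and integer delays.
meso_prepare <- function(spec, settings) {
  M <- n_populations(spec)
  N <- pop_sizes(spec)
  dt <- settings$dt
  hT <- resolve_history(spec, settings)
  out <- vector("list", M)
  for (a in seq_len(M)) {
    pop <- spec$populations[[a]]
    K <- as.integer(round(hT[a] / dt))
    k_ref <- max(1L, as.integer(round(pop$t_ref / dt)))
    if (abs(k_ref * dt - pop$t_ref) > 1e-9) {
      message(sprintf(
        "population %d: t_ref = %g s is not a multiple of dt; using %d step(s)",
        a, pop$t_ref, k_ref))
    }
    lags <- (0:(K + 1)) * dt
    theta_tab <- numeric(K + 2)
    tail <- lags >= pop$t_ref - 1e-12
    if (any(tail) && n_components(pop$theta)) {
      theta_tab[tail] <- theta_kernel_eval(pop$theta, pmax(lags[tail], pop$t_ref))
    }
    qr_tab <- quasi_renewal_kernel(pop$theta, pmax(lags, 1e-300),
                                   pop$delta_u) / pop$N
    qr_tab[1] <- 0 # lag 0 never contributes
    eta_tab <- numeric(K + 2)
    if (!is_empty_kernel(pop$eta)) {
      for (l in seq_along(pop$eta$J)) {
        eta_tab <- eta_tab +
          (pop$eta$J[l] / pop$eta$tau[l]) * exp(-lags / pop$eta$tau[l])
      }
    }
    nth <- n_components(pop$theta)
    g_decay <- if (nth) exp(-dt / pop$theta$tau) else numeric(0)
    g_w <- if (nth) pop$theta$J * exp(-(K * dt) / pop$theta$tau) else numeric(0)
    em <- exp(-dt / pop$tau_m)
    es <- exp(-dt / spec$tau_s)
    coefY <- numeric(M)
    for (b in seq_len(M)) {
      if (abs(spec$tau_s[b] - pop$tau_m) < 1e-9) {
        coefY[b] <- dt * em
      } else {
        coefY[b] <- pop$tau_m * spec$tau_s[b] / (spec$tau_s[b] - pop$tau_m) *
          (es[b] - em)
      }
    }
    delay_steps <- pmax(1L, as.integer(round(spec$delay[a, ] / dt)))
    if (any(abs(delay_steps * dt - spec$delay[a, ]) > 1e-9)) {
      message(sprintf(
        "population %d: delays rounded to integer multiples of dt", a))
    }
    out[[a]] <- list(
      N = as.numeric(pop$N), K = K, k_ref = k_ref,
      variant = if (pop$model_variant == "GIF") 0L else 1L,
      u_th = pop$u_th, u_r = pop$u_r, u_rest = pop$u_rest,
      c = pop$c, delta_u = pop$delta_u, em = em,
      coefA = pop$tau_m * (1 - em),
      theta_tab = theta_tab, qr_tab = qr_tab, eta_tab = eta_tab,
      g_decay = g_decay, g_w = g_w,
      Jcoup = spec$p[a, ] * N * spec$w[a, ],
      es = es, coefY = coefY, delay_steps = delay_steps)
  }
  out
}

stimulus_matrix <- function(spec, settings, n_steps, n_warm) {
  M <- n_populations(spec)
  times <- ((0:(n_steps + n_warm - 1)) - n_warm) * settings$dt
  stim <- matrix(0, length(times), M)
  for (a in seq_len(M)) {
    stim[, a] <- eval_stimulus(spec$stimulus[[a]], times)
  }
  stim
}

#' Integrate the stochastic mesoscopic population equations
#'
#' Evolves, for every population, the expected survival numbers
#' \eqn{\bar m_k} and their variances \eqn{v_k} over an explicit
#' refractory history of `K` bins, the free-neuron pool `(x, z)`, the free
#' membrane potential, quasi-renewal thresholds and synaptic filters, and
#' draws one spike count per population per time step from the expected
#' count \eqn{\bar{\Delta n}} (binomial by default). This reproduces the
#' statistics of the full microscopic network at a cost independent of the
#' number of neurons. The initial condition is set by `settings$init`
#' (synchronized, free, or the asynchronous stationary state); a
#' deterministic burn-in of length `settings$warmup` can be prepended to
#' relax transients before recording.
#'
#' @param spec a [network_spec()].
#' @param settings a [sim_settings()].
#' @param validate check the time step with [validate_dt()] first.
#' @param record_free_potential also record the free membrane potential
#'   and free threshold (used by diagnostics).
#' @return An [activity_trace()]; if `settings$record_expected` it carries
#'   the expected activity \eqn{\bar A(t)} in field `expected`.
#' @examples
#' pre <- preset_uncoupled_lif(mu = 30, N = 500)
#' tr <- run_meso(pre$spec, sim_settings(dt = 5e-4, duration = 0.5, seed = 1))
#' colMeans(tr$activity)
#' @export
run_meso <- function(spec, settings, validate = TRUE,
                     record_free_potential = FALSE) {
  stopifnot(inherits(spec, "network_spec"), inherits(settings, "sim_settings"))
  if (validate) validate_dt(spec, settings$dt, probe = FALSE)
  n_steps <- as.integer(round(settings$duration / settings$dt))
  n_warm <- as.integer(round(settings$warmup / settings$dt))
  pops <- meso_prepare(spec, settings)
  stim <- stimulus_matrix(spec, settings, n_steps, n_warm)
  state0 <- NULL
  A_pre <- numeric(n_populations(spec))
  if (identical(settings$init, "stationary")) {
    r0 <- stationary_rates(spec, settings)
    state0 <- build_stationary_state(spec, settings, r0)$states
    A_pre <- r0
  }
  res <- with_seed(settings$seed,
    meso_run_cpp(pops, stim, n_steps, n_warm, settings$dt,
                 sampling_mode_code(settings$sampling),
                 settings$record_expected, record_free_potential,
                 identical(settings$init, "free"), state0, A_pre))
  nm <- vapply(spec$populations, function(q) q$name %||% "", "")
  tr <- activity_trace(settings$dt, res$counts, pop_sizes(spec),
                       expected = res$expected,
                       pop_names = if (all(nzchar(nm))) nm else NULL)
  if (record_free_potential) {
    tr$free_potential <- res$free_potential
    tr$free_threshold <- res$free_threshold
  }
  tr
}

#' Variance-weighted effective firing probability
#'
#' The firing probability assigned to the normalization deficit of the
#' mesoscopic pseudo-density ("holes and overshoots"):
#' \deqn{P_\Lambda = \frac{\sum_k P_\lambda(t|t_k) v_k + P_{free}\, z}
#'   {\sum_k v_k + z}.}
#' It is the average of the per-state firing probabilities weighted by the
#' survival-number variances, i.e. by where fluctuations actually live.
#' When all variances vanish (e.g. immediately after full
#' synchronization) the deficit is zero and any bounded choice works; the
#' free-neuron probability is returned as the large-N-consistent value.
#'
#' @param P_lambda firing probabilities of the refractory states.
#' @param P_free firing probability of free neurons.
#' @param v survival-number variances of the refractory states.
#' @param z summed variance of the free states.
#' @return the effective firing probability \eqn{P_\Lambda}.
#' @export
effective_probability <- function(P_lambda, P_free, v, z) {
  stopifnot(length(P_lambda) == length(v), all(v >= 0), z >= 0)
  denom <- sum(v) + z
  if (denom <= 0) return(P_free)
  (sum(P_lambda * v) + P_free * z) / denom
}

#' Expected spike count of one time step
#'
#' \deqn{\bar{\Delta n} = \sum_k P_\lambda \bar m_k + P_{free}\, x +
#'   P_\Lambda \left(N - \sum_k \bar m_k - x\right),}
#' clipped to `[0, N]` before sampling. The last term corrects for the
#' normalization deficit of the pseudo-density; it vanishes when the
#' expected survival numbers add up to `N` exactly.
#'
#' @param m_bar expected survival numbers of the refractory states.
#' @param x expected number of free neurons.
#' @param P_lambda,P_free,P_Lambda firing probabilities (see
#'   [effective_probability()]).
#' @param N population size.
#' @return expected spike count in `[0, N]`.
#' @export
expected_spike_count <- function(m_bar, x, P_lambda, P_free, P_Lambda, N) {
  stopifnot(length(m_bar) == length(P_lambda))
  dn_bar <- sum(P_lambda * m_bar) + P_free * x +
    P_Lambda * (N - sum(m_bar) - x)
  min(max(dn_bar, 0), N)
}

#' Sample a spike count from its expected value
#'
#' @param dn_bar expected spike count in `[0, N]`.
#' @param N population size.
#' @param mode `"binomial"` (\eqn{B(N, \bar{\Delta n}/N)}, default),
#'   `"poisson"` (truncated at `N`), `"gaussian"` (mean
#'   \eqn{\bar{\Delta n}}, variance \eqn{\bar{\Delta n}}, rounded and
#'   clipped) or `"expected"` (returns `dn_bar` unchanged).
#' @return sampled spike count.
#' @export
sample_activity <- function(dn_bar, N,
                            mode = c("binomial", "poisson", "gaussian",
                                     "expected")) {
  mode <- match.arg(mode)
  if (dn_bar < 0 || dn_bar > N) stop("dn_bar must lie in [0, N]")
  if (mode == "expected") return(dn_bar)
  if (dn_bar == 0) return(0)
  out <- switch(mode,
    binomial = stats::rbinom(1L, size = as.integer(round(N)),
                             prob = dn_bar / N),
    poisson = stats::rpois(1L, dn_bar),
    gaussian = floor(dn_bar + sqrt(dn_bar) * stats::rnorm(1L) + 0.5))
  min(max(out, 0), N)
}

#' One moment-update step of the mesoscopic integrator
#'
#' Applies the survival-number mean and variance recursions
#' \deqn{\bar m_k \leftarrow (1 - P_\lambda)\bar m_k, \qquad
#'   v_k \leftarrow (1 - P_\lambda)^2 v_k + P_\lambda \bar m_k,}
#' absorbs the oldest refractory bin into the free pool
#' (\eqn{x \leftarrow (1 - P_{free})x + \bar m_{oldest}},
#' \eqn{z \leftarrow (1-P_{free})^2 z + P_{free} x + v_{oldest}}) and
#' applies the boundary conditions of the newly created bin
#' (\eqn{\bar m = \Delta n}, \eqn{v = 0}).
#'
#' @param m_bar,v survival-number means/variances ordered oldest first.
#' @param x,z free-pool mean and variance.
#' @param P_lambda per-state firing probabilities (same order).
#' @param P_free free-neuron firing probability.
#' @param dn spike count of the current bin (enters as the new cohort).
#' @return list with updated `m_bar`, `v` (same length, oldest dropped,
#'   new bin appended), `x` and `z`.
#' @export
update_moments <- function(m_bar, v, x, z, P_lambda, P_free, dn) {
  stopifnot(length(m_bar) == length(v), length(m_bar) == length(P_lambda))
  q <- 1 - P_lambda
  m_new <- q * m_bar
  v_new <- q^2 * v + P_lambda * m_bar
  x_new <- (1 - P_free) * x + m_new[1]
  z_new <- (1 - P_free)^2 * z + P_free * x + v_new[1]
  list(m_bar = c(m_new[-1], dn), v = c(v_new[-1], 0),
       x = x_new, z = z_new)
}
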