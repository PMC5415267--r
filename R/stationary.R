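# Construction of the asynchronous stationary state of the mesoscopic
# integrator, and the self-consistent stationary rates.
#
# Given candidate stationary rates r (one per population), the state is
# built from the integrator's own discretized quantities: constant
# activity history dn = N r dt, membrane potentials relaxing from the
# reset, quasi-renewal thresholds under a constant activity, survival
# numbers from the discrete survival recursion, the free pool from exact
# normalization, and the variance buffers from their stationary
# recursions. The implied output rate of this state defines a map whose
# fixed point is the mean-field stationary solution.

build_stationary_state <- function(spec, settings, r, rates_only = FALSE,
                                   pops = meso_prepare(spec, settings)) {
  M <- n_populations(spec)
  dt <- settings$dt
  states <- vector("list", M)
  r_out <- numeric(M)
  for (a in seq_len(M)) {
    pp <- pops[[a]]
    K <- pp$K
    D <- pp$N * r[a] * dt
    mu_star <- pp$u_rest + sum(pp$Jcoup * pp$coefA / (1 - pp$em) * r)
    g <- rep(r[a], length(pp$g_decay))
    th_free <- pp$u_th + sum(pp$g_w * g)
    # quantities indexed by lag j = 1..K+1 (time since last spike = j*dt)
    jj <- 1:(K + 1)
    u_lag <- ifelse(jj <= pp$k_ref, pp$u_r,
                    mu_star + (pp$u_r - mu_star) * pp$em^(jj - pp$k_ref))
    if (pp$variant == 1L) u_lag <- mu_star + pp$eta_tab[jj + 1L]
    qr <- pp$qr_tab          # theta_tilde(lag * dt) / N, index lag + 1
    th_hat <- th_free + D * (rev(cumsum(rev(c(qr[(2:K) + 1L], 0)))))
    th_hat <- c(th_hat, th_free)  # lag K+1: no younger... older bins left
    lam <- ifelse(jj > pp$k_ref,
                  pp$c * exp(pmin((u_lag - th_hat -
                                   pp$theta_tab[jj + 1L]) / pp$delta_u, 20)),
                  0)
    P <- 1 - exp(-0.5 * (lam[1:K] + lam[2:(K + 1)]) * dt)
    m <- D * c(1, cumprod(1 - P[seq_len(K - 1)]))
    # normalize: survivors plus free pool must equal N. An overcomplete
    # candidate (sum m > N, i.e. the trial rate is too high for the
    # implied survival profile) is projected back by rescaling.
    if (sum(m) > pp$N) m <- m * (pp$N / sum(m))
    x <- max(pp$N - sum(m), 0)
    lam_free <- pp$c * exp(pmin((mu_star - th_free) / pp$delta_u, 20))
    P_free <- 1 - exp(-lam_free * dt)
    # implied output rate of this state (normalization makes the
    # correction term vanish)
    r_out[a] <- (sum(P * m) + P_free * x) / (pp$N * dt)
    if (rates_only) {
      states <- NULL
    } else {
      v <- numeric(K)
      for (j in seq_len(K - 1)) {
        v[j + 1] <- (1 - P[j])^2 * v[j] + P[j] * m[j]
      }
      v_out <- (1 - P[K])^2 * v[K] + P[K] * m[K]
      z <- (P_free * x + v_out) / max(1 - (1 - P_free)^2, 1e-12)
      # map lag j to the circular-buffer slot of bin -j at l = 0
      slot <- ((-(1:K)) %% K) + 1L
      st <- list(m = numeric(K), v = numeric(K), u = numeric(K),
                 lam = numeric(K), dn = numeric(K))
      st$m[slot] <- m
      st$v[slot] <- v
      st$u[slot] <- u_lag[1:K]
      st$lam[slot] <- lam[1:K]
      st$dn[slot] <- D
      st$g <- g
      st$y <- r
      st$h <- mu_star
      st$lam_free <- lam_free
      st$x <- x
      st$z <- z
      states[[a]] <- st
    }
  }
  list(states = states, r_out = r_out)
}

#' Self-consistent stationary rates of the mean-field dynamics
#'
#' Computes the asynchronous stationary firing rates of all populations
#' by damped fixed-point iteration of the integrator's own discretized
#' stationary map: each population's output rate is the expected spike
#' count of the stationary refractory density (membrane potential
#' relaxing from reset under the mean recurrent input, quasi-renewal
#' threshold under constant activity). Fluctuation corrections are not
#' included, so in strongly fluctuating networks the realized stochastic
#' rates can differ somewhat.
#'
#' @param spec a [network_spec()].
#' @param settings a [sim_settings()] (for `dt` and history length).
#' @param r_init optional initial rate vector (1/s); defaults to 1 Hz.
#' @param iters,damp iteration count and damping factor.
#' @param tol convergence tolerance on the rates (1/s).
#' @return numeric vector of stationary rates in 1/s.
#' @export
stationary_rates <- function(spec, settings, r_init = NULL, iters = 3000,
                             damp = 0.2, tol = 1e-8) {
  M <- n_populations(spec)
  r <- if (is.null(r_init)) rep(1, M) else rep_len(r_init, M)
  pops <- meso_prepare(spec, settings)
  # damped fixed-point iteration with per-population step adaptation:
  # the step is halved whenever the update direction flips (oscillating
  # loop gain) and slowly recovered otherwise
  step <- rep(damp, M)
  delta_prev <- rep(0, M)
  for (i in seq_len(iters)) {
    out <- build_stationary_state(spec, settings, r, rates_only = TRUE,
                                  pops = pops)$r_out
    delta <- out - r
    flip <- delta * delta_prev < 0
    step[flip] <- step[flip] * 0.5
    step[!flip] <- pmin(step[!flip] * 1.02, damp)
    delta_prev <- delta
    r <- r + step * delta
    if (max(abs(delta)) < tol) return(pmax(r, 0))
  }
  warning("stationary-rate iteration did not converge to tolerance")
  pmax(r, 0)
}
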