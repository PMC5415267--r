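#' Pure-R reference implementation of the mesoscopic integrator
#'
#' A transparent, slow implementation of exactly the same update step as
#' [run_meso()], intended for validation and inspection on small
#' problems. It performs the same sequence of random draws, so with
#' identical `spec`, `settings` and seed its trajectory is identical to
#' the compiled integrator. With `brute_force = TRUE` the quasi-renewal
#' threshold of each refractory state is obtained by direct summation of
#' the kernel over the whole explicit history instead of the O(K)
#' iterative sweep; both routes must agree to machine precision.
#'
#' @inheritParams run_meso
#' @param brute_force recompute the partial quasi-renewal thresholds by
#'   direct summation (O(K^2) per step).
#' @return An [activity_trace()] with the expected activity attached.
#' @export
run_meso_reference <- function(spec, settings, brute_force = FALSE) {
  stopifnot(inherits(spec, "network_spec"), inherits(settings, "sim_settings"))
  M <- n_populations(spec)
  dt <- settings$dt
  n_steps <- as.integer(round(settings$duration / dt))
  n_warm <- as.integer(round(settings$warmup / dt))
  n_tot <- n_steps + n_warm
  pops <- meso_prepare(spec, settings)
  stim <- stimulus_matrix(spec, settings, n_steps, n_warm)
  mode_code <- sampling_mode_code(settings$sampling)

  st <- lapply(pops, function(pp) {
    K <- pp$K
    s <- list(m = numeric(K), v = numeric(K), u = rep(pp$u_r, K),
              lam = numeric(K), dn = numeric(K),
              g = numeric(length(pp$g_decay)), y = numeric(M),
              h = pp$u_rest, x = 0, z = 0)
    s$lam_free <- pp$c * exp(pmin((s$h - pp$u_th) / pp$delta_u, 20))
    if (identical(settings$init, "free")) {
      s$x <- pp$N
    } else {
      slot <- ((-1) %% K) + 1L
      s$m[slot] <- pp$N
      s$dn[slot] <- pp$N
    }
    s
  })
  A <- matrix(0, n_tot + 1, M)
  if (!identical(settings$init, "free")) A[1, ] <- 1 / dt
  counts <- matrix(0, n_steps, M)
  expected <- matrix(0, n_steps, M)

  hazard <- function(u, th, c, du) c * exp(pmin((u - th) / du, 20))

  with_seed(settings$seed, {
    for (l in 0:(n_tot - 1)) {
      mode <- if (l < n_warm) 3L else mode_code
      for (a in seq_len(M)) {
        pp <- pops[[a]]
        s <- st[[a]]
        K <- pp$K
        # synaptic input (exact one-step solution)
        h_tot <- stim[l + 1, a] * (1 - pp$em)
        for (b in seq_len(M)) {
          idx <- l - pp$delay_steps[b] + 2L
          Ad <- if (idx >= 1) A[idx, b] else 0
          if (pp$Jcoup[b] != 0) {
            h_tot <- h_tot +
              pp$Jcoup[b] * (Ad * pp$coefA + (s$y[b] - Ad) * pp$coefY[b])
          }
          s$y[b] <- Ad + (s$y[b] - Ad) * pp$es[b]
        }
        # free neurons
        slot_old <- (l %% K) + 1L
        A_old <- s$dn[slot_old] / (pp$N * dt)
        if (length(s$g)) {
          s$g <- s$g * pp$g_decay + A_old * (1 - pp$g_decay)
        }
        th_free <- pp$u_th + sum(pp$g_w * s$g)
        h_new <- pp$u_rest + (s$h - pp$u_rest) * pp$em + h_tot
        lam_free_new <- hazard(h_new, th_free, pp$c, pp$delta_u)
        P_free <- 1 - exp(-0.5 * (s$lam_free + lam_free_new) * dt)
        # refractory states k = l-K .. l-1 (oldest first)
        ks <- (l - K):(l - 1)
        slots <- (ks %% K) + 1L
        lag_next <- (l + 1) - ks
        elapsed <- l - ks
        if (pp$variant == 0L) {
          evolve <- elapsed >= pp$k_ref
          s$u[slots[evolve]] <- pp$u_rest +
            (s$u[slots[evolve]] - pp$u_rest) * pp$em + h_tot
          s$u[slots[!evolve]] <- pp$u_r
          u_val <- s$u[slots]
        } else {
          u_val <- h_new + pp$eta_tab[lag_next + 1L]
        }
        # partial quasi-renewal thresholds at the advanced time
        if (brute_force) {
          # direct summation: th_hat_k = th_free + sum_{k' < k} qr(lag)*dn(k')
          th_hat <- numeric(K)
          for (j in seq_len(K)) {
            th_hat[j] <- th_free
            if (j > 1) {
              kk <- ks[seq_len(j - 1)]
              th_hat[j] <- th_free +
                sum(pp$qr_tab[(l + 1) - kk + 1L] * s$dn[(kk %% K) + 1L])
            }
          }
          # the free threshold at t_{l+1} already contains the oldest bin
          # through the g-variables; remove its double count as in the
          # sweep initialization
          th_hat <- th_hat - pp$qr_tab[K + 2L] * s$dn[slot_old]
        } else {
          th_hat <- numeric(K)
          acc <- th_free - pp$qr_tab[K + 2L] * s$dn[slot_old]
          for (j in seq_len(K)) {
            th_hat[j] <- acc
            acc <- acc + pp$qr_tab[lag_next[j] + 1L] * s$dn[slots[j]]
          }
        }
        lam_new <- ifelse(elapsed + 1 > pp$k_ref,
                          hazard(u_val, th_hat + pp$theta_tab[lag_next + 1L],
                                 pp$c, pp$delta_u),
                          0)
        P_lam <- 1 - exp(-0.5 * (s$lam[slots] + lam_new) * dt)
        s$lam[slots] <- lam_new
        m_cur <- s$m[slots]
        v_cur <- s$v[slots]
        P_Lam <- effective_probability(P_lam, P_free, v_cur, s$z)
        dn_bar <- expected_spike_count(m_cur, s$x, P_lam, P_free, P_Lam, pp$N)
        dn_new <- if (mode == 3L) dn_bar else {
          if (dn_bar <= 0) 0 else switch(mode + 1L,
            stats::rbinom(1L, as.integer(pp$N), dn_bar / pp$N),
            min(stats::rpois(1L, dn_bar), pp$N),
            min(max(floor(dn_bar + sqrt(dn_bar) * stats::rnorm(1L) + 0.5),
                    0), pp$N))
        }
        # moment updates; oldest bin is absorbed into the free pool
        q <- 1 - P_lam
        m_upd <- q * m_cur
        v_upd <- q^2 * v_cur + P_lam * m_cur
        z_new <- (1 - P_free)^2 * s$z + P_free * s$x + v_upd[1]
        s$x <- (1 - P_free) * s$x + m_upd[1]
        s$z <- z_new
        s$m[slots] <- m_upd
        s$v[slots] <- v_upd
        # boundary conditions of the new bin
        s$m[slot_old] <- dn_new
        s$v[slot_old] <- 0
        s$u[slot_old] <- pp$u_r
        s$lam[slot_old] <- 0
        s$dn[slot_old] <- dn_new
        s$h <- h_new
        s$lam_free <- lam_free_new
        A[l + 2L, a] <- dn_new / (pp$N * dt)
        if (l >= n_warm) {
          counts[l - n_warm + 1L, a] <- dn_new
          expected[l - n_warm + 1L, a] <- dn_bar / (pp$N * dt)
        }
        st[[a]] <- s
      }
    }
  })
  nm <- vapply(spec$populations, function(q) q$name %||% "", "")
  activity_trace(dt, counts, pop_sizes(spec), expected = expected,
                 pop_names = if (all(nzchar(nm))) nm else NULL)
}
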