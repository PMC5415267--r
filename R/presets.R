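new_preset <- function(name, spec, settings, description) {
  structure(list(name = name, spec = spec, settings = settings,
                 description = description),
            class = "preset")
}

#' @export
print.preset <- function(x, ...) {
  cat(sprintf("<preset> '%s': %s\n", x$name, x$description))
  print(x$spec)
  invisible(x)
}

#' Uncoupled population of leaky integrate-and-fire neurons
#'
#' A single population of `N` non-adapting LIF neurons with escape noise
#' and no synaptic coupling, driven by a constant potential `mu` (in mV,
#' relative to rest). With `step_time` set, the drive instead starts at a
#' baseline of 15 mV and steps up to `mu` at `step_time`. In the
#' stationary state the spike trains are renewal processes, so the
#' population spectrum is known analytically ([renewal_spectrum()]).
#'
#' @param mu stationary drive in mV (default 30).
#' @param N population size (default 500).
#' @param step_time optional step onset in s.
#' @param dt,duration,seed bundled simulation settings.
#' @return A `preset` (list with `spec`, `settings`, `name`,
#'   `description`).
#' @export
preset_uncoupled_lif <- function(mu = 30, N = 500, step_time = NULL,
                                 dt = 2e-4, duration = 10, seed = 1L) {
  if (is.null(step_time)) {
    u_rest <- mu
    stim <- NULL
  } else {
    u_rest <- 15
    stim <- list(step_stimulus(step_time, 1e9, mu - 15))
  }
  pop <- population_params(N = N, u_rest = u_rest, name = "LIF")
  spec <- network_spec(list(pop), p = matrix(0, 1, 1), w = matrix(0, 1, 1),
                       delay = 0.001, tau_s = 0.003, stimulus = stim)
  new_preset("uncoupled_lif", spec,
             sim_settings(dt = dt, duration = duration, seed = seed),
             sprintf("uncoupled non-adapting LIF population, N = %d, mu = %g mV",
                     N, mu))
}

#' Adapting or bursty single population
#'
#' `kind = "adapting"`: neurons with a two-exponential positive threshold
#' kernel (fast + 1 s component, 1.5 mV s each), depolarized reset
#' (`u_r = 25` mV above `u_th = 10` mV) and drive stepping from 12 to
#' 27 mV at `step_time` (constant at `mu_high` if `step_time` is
#' `NULL`). `kind = "bursty"`: a biphasic kernel combining facilitation
#' (-0.45 mV s at 50 ms) and adaptation (2.5 mV s at 1 s) with a fast
#' membrane (`tau_m = 10` ms), producing burst firing with a bimodal ISI
#' density.
#'
#' @param kind `"adapting"` or `"bursty"`.
#' @param N population size.
#' @param mu_high stationary drive in mV (adapting kind).
#' @param step_time optional step onset in s (adapting kind).
#' @param dt,duration,seed bundled simulation settings.
#' @return A `preset`.
#' @export
preset_adapting <- function(kind = c("adapting", "bursty"), N = 500,
                            mu_high = 27, step_time = NULL,
                            dt = 2e-4, duration = 10, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "adapting") {
    th <- adaptation_kernel(J = c(1.5, 1.5), tau = c(0.01, 1), t_ref = 0.004)
    if (is.null(step_time)) {
      u_rest <- mu_high
      stim <- NULL
    } else {
      u_rest <- 12
      stim <- list(step_stimulus(step_time, 1e9, mu_high - 12))
    }
    pop <- population_params(N = N, u_th = 10, u_r = 25, u_rest = u_rest,
                             theta = th, name = "adapting")
  } else {
    th <- adaptation_kernel(J = c(-0.45, 2.5), tau = c(0.05, 1),
                            t_ref = 0.004)
    stim <- NULL
    pop <- population_params(N = N, tau_m = 0.01, u_th = 10, u_r = 0,
                             u_rest = 20, theta = th, name = "bursty")
  }
  spec <- network_spec(list(pop), p = matrix(0, 1, 1), w = matrix(0, 1, 1),
                       delay = 0.001, tau_s = 0.003, stimulus = stim)
  new_preset(kind, spec,
             sim_settings(dt = dt, duration = duration, seed = seed),
             sprintf("%s single population, N = %d", kind, N))
}

#' Fully or randomly connected excitatory-inhibitory network
#'
#' Two populations with \eqn{N^E = 4N/5} excitatory and
#' \eqn{N^I = N/5} inhibitory LIF neurons, each neuron receiving
#' \eqn{C^E = pN^E} excitatory and \eqn{C^I = pN^I} inhibitory synapses.
#' Synaptic strengths are `w` (excitatory) and `-5 w` (inhibitory); by
#' default `w` is scaled so that the total coupling `C w` is the same as
#' for the reference configuration `C = 200`, `w = 0.3` mV, which keeps
#' the mean synaptic input constant when `N` or `p` are rescaled. Drive
#' 24 mV to both populations; `delta_u = 2.5` mV, no adaptation.
#'
#' @param N total number of neurons (divisible by 5).
#' @param p connection probability; alternatively give `C`, the total
#'   in-degree (`p = C/N`).
#' @param C optional total number of synapses per neuron.
#' @param w optional excitatory weight in mV, overriding the `Cw = const`
#'   scaling.
#' @param mu drive in mV for both populations.
#' @param dt,duration,seed bundled simulation settings.
#' @return A `preset`.
#' @export
preset_ei_network <- function(N = 250, p = 1, C = NULL, w = NULL, mu = 24,
                              dt = 2e-4, duration = 10, seed = 1L) {
  if (N %% 5 != 0) stop("N must be divisible by 5 (N_I = N_E/4)")
  if (!is.null(C)) p <- C / N
  if (p < 0 || p > 1) stop("connection probability p = C/N must be in [0, 1]")
  C_tot <- p * N
  if (is.null(w)) w <- 0.3 * 200 / C_tot
  NE <- 4L * N %/% 5L
  NI <- N %/% 5L
  popE <- population_params(N = NE, u_rest = mu, delta_u = 2.5, name = "E")
  popI <- population_params(N = NI, u_rest = mu, delta_u = 2.5, name = "I")
  pmat <- matrix(p, 2, 2)
  wmat <- matrix(c(w, w, -5 * w, -5 * w), 2, 2) # columns: source E, I
  spec <- network_spec(list(popE, popI), p = pmat, w = wmat, delay = 0.001,
                       tau_s = c(0.003, 0.006))
  new_preset("ei_network", spec,
             sim_settings(dt = dt, duration = duration, seed = seed),
             sprintf("E-I network, N = %d, p = %.3g, C = %.3g, w = %.4g mV",
                     N, p, C_tot, w))
}

#' Winner-take-all network of two competing excitatory populations
#'
#' Two excitatory populations (`N = 400` each) compete through a common
#' inhibitory population (`N = 200`); all present connections are fully
#' connected (`p = 1`). Each excitatory population excites itself and
#' the inhibitory population; the inhibitory population inhibits both
#' excitatory populations and itself; the two excitatory populations are
#' not directly coupled, so competition is purely inhibitory. The
#' network is bistable (one excitatory population active at a time) and
#' finite-size fluctuations induce switching. Without adaptation the
#' weights are \eqn{w^E = 0.0624} mV, \eqn{w^I = -0.2496} mV and the
#' drive is 36 mV; with weak, slow adaptation on the excitatory neurons
#' (`J_theta = 0.1` mV s, `tau_theta = 1` s) the weights are
#' \eqn{w^E = 0.096} mV, \eqn{w^I = -0.384} mV and the excitatory drive
#' 36.5 mV, which makes the switching markedly more regular.
#'
#' @param adaptation logical; add the slow adaptation component to the
#'   excitatory populations.
#' @param dt,duration,seed bundled simulation settings.
#' @return A `preset`.
#' @export
preset_bistable <- function(adaptation = FALSE, dt = 2e-4, duration = 20,
                            seed = 1L) {
  if (adaptation) {
    wE <- 0.096; wI <- -0.384; muE <- 36.5
    thE <- adaptation_kernel(J = 0.1, tau = 1, t_ref = 0.004)
  } else {
    wE <- 0.0624; wI <- -0.2496; muE <- 36
    thE <- NULL
  }
  mk_e <- function(nm) population_params(N = 400, u_rest = muE,
                                         delta_u = 2.5, theta = thE,
                                         name = nm)
  popI <- population_params(N = 200, u_rest = 36, delta_u = 2.5, name = "I")
  # rows = target (E1, E2, I); columns = source
  pmat <- rbind(c(1, 0, 1),
                c(0, 1, 1),
                c(1, 1, 1))
  wmat <- rbind(c(wE, 0, wI),
                c(0, wE, wI),
                c(wE, wE, wI))
  spec <- network_spec(list(mk_e("E1"), mk_e("E2"), popI), p = pmat,
                       w = wmat, delay = 0.001, tau_s = c(0.003, 0.003, 0.006))
  new_preset("bistable", spec,
             sim_settings(dt = dt, duration = duration, seed = seed),
             sprintf("winner-take-all network, %s adaptation",
                     if (adaptation) "with" else "without"))
}

column_table <- function() {
  nm <- c("L2/3e", "L2/3i", "L4e", "L4i", "L5e", "L5i", "L6e", "L6i")
  p <- rbind(
    c(0.1009, 0.1689, 0.0437, 0.0818, 0.0323, 0.0,    0.0076, 0.0),
    c(0.1346, 0.1371, 0.0316, 0.0515, 0.0755, 0.0,    0.0042, 0.0),
    c(0.0077, 0.0059, 0.0497, 0.135,  0.0067, 0.0003, 0.0453, 0.0),
    c(0.0691, 0.0029, 0.0794, 0.1597, 0.0033, 0.0,    0.1057, 0.0),
    c(0.1004, 0.0622, 0.0505, 0.0057, 0.0831, 0.3726, 0.0204, 0.0),
    c(0.0548, 0.0269, 0.0257, 0.0022, 0.06,   0.3158, 0.0086, 0.0),
    c(0.0156, 0.0066, 0.0211, 0.0166, 0.0572, 0.0197, 0.0396, 0.2252),
    c(0.0364, 0.001,  0.0034, 0.0005, 0.0277, 0.008,  0.0658, 0.1443))
  dimnames(p) <- list(nm, nm)
  list(
    names = nm,
    N = c(20683L, 5834L, 21915L, 5479L, 4850L, 1065L, 14395L, 2948L),
    mu_hat = c(19.149, 20.362, 30.805, 28.069, 29.437, 29.33, 34.932, 32.081),
    r_hat = c(0.974, 2.861, 4.673, 5.65, 8.141, 9.013, 0.988, 7.53),
    u_rest_adapt = c(20.123, 20.362, 35.478, 28.069, 37.578, 29.33, 35.92,
                     32.081),
    stim_RI = c(0, 0, 19, 11.964, 0, 0, 9.896, 3.788),
    p = p)
}

#' Eight-population cortical-column model
#'
#' A laminar cortical microcircuit of four layers (L2/3, L4, L5, L6),
#' each with an excitatory and an inhibitory population (77,169 neurons
#' in total), with empirically derived population sizes and connection
#' probabilities. The background input of the original network model is
#' replaced by a constant drive together with an increased escape noise
#' (`delta_u = 5` mV); the per-population resting potentials are fitted
#' values that reproduce the target spontaneous rates. Synaptic weights
#' are 0.176 mV for excitatory sources (doubled, 0.351 mV, for the
#' L4e-to-L2/3e projection) and -0.702 mV for inhibitory sources;
#' `tau_m = 10` ms,
#' `tau_s = 0.5` ms, delay 1.5 ms, `t_ref = 2` ms, `u_th = 15` mV,
#' `u_r = 0` mV.
#'
#' With `with_adaptation = TRUE`, excitatory neurons get a slow
#' adaptation component (`J_theta = 1` mV s, `tau_theta = 1` s) and the
#' resting potentials are raised by `J_theta` times the target rate,
#' which restores the same stationary rates. With
#' `with_stimulus = TRUE`, a step drive mimicking thalamic input (19 mV
#' to L4e, 11.964 mV to L4i, 9.896 mV to L6e, 3.788 mV to L6i) is
#' applied during `[0.06, 0.09)` s.
#'
#' @param with_adaptation add adaptation to the excitatory populations.
#' @param with_stimulus add the thalamic step stimulus.
#' @param dt,duration,seed bundled simulation settings (mesoscopic
#'   default `dt = 0.5` ms).
#' @return A `preset`. The fitted target rates are attached as
#'   `$target_rates` (1/s).
#' @export
preset_cortical_column <- function(with_adaptation = FALSE,
                                   with_stimulus = FALSE,
                                   dt = 5e-4, duration = 10, seed = 1L) {
  tab <- column_table()
  M <- 8L
  u_rest <- if (with_adaptation) tab$u_rest_adapt else tab$mu_hat
  pops <- vector("list", M)
  for (a in seq_len(M)) {
    excitatory <- a %% 2L == 1L
    th <- if (with_adaptation && excitatory) {
      adaptation_kernel(J = 1.0, tau = 1.0, t_ref = 0.002)
    } else {
      adaptation_kernel(t_ref = 0.002)
    }
    pops[[a]] <- population_params(
      N = tab$N[a], tau_m = 0.01, t_ref = 0.002, u_th = 15, u_r = 0,
      u_rest = u_rest[a], c = 10, delta_u = 5, theta = th,
      name = tab$names[a])
  }
  w <- matrix(rep(c(0.176, -0.702), 4), nrow = M, ncol = M, byrow = TRUE)
  w[1, 3] <- 0.351 # doubled weight of the L4e -> L2/3e projection
  stim <- NULL
  if (with_stimulus) {
    stim <- lapply(seq_len(M), function(a) {
      if (tab$stim_RI[a] != 0) step_stimulus(0.06, 0.09, tab$stim_RI[a])
      else NULL
    })
  }
  spec <- network_spec(pops, p = tab$p, w = w, delay = 0.0015,
                       tau_s = rep(5e-4, M), stimulus = stim)
  pre <- new_preset("cortical_column", spec,
                    sim_settings(dt = dt, duration = duration, seed = seed),
                    sprintf("8-population cortical column, %s adaptation, %s stimulus",
                            if (with_adaptation) "with" else "without",
                            if (with_stimulus) "with" else "without"))
  pre$target_rates <- tab$r_hat
  pre
}

#' Synthetic traces for testing the analysis tools
#'
#' Generates controlled inputs with known statistics, without running a
#' simulator: `"poisson"` - a population of `N` independent Poisson
#' neurons at a given rate (flat spectrum `rate/N`); `"telegraph"` - two
#' anti-phase populations switching between two activity levels with
#' exponentially distributed residence times (memoryless switching, CV of
#' residence times 1); `"square_wave"` - deterministic anti-phase
#' alternation with half-period `period/2`.
#'
#' @param kind one of `"poisson"`, `"telegraph"`, `"square_wave"`.
#' @param seed RNG seed.
#' @param N population size per column.
#' @param rate Poisson rate in 1/s (`"poisson"` kind).
#' @param levels low/high activity levels in 1/s (switching kinds).
#' @param switch_rate switching rate in 1/s (`"telegraph"`).
#' @param period full period in s (`"square_wave"`).
#' @param dt bin width in s.
#' @param duration trace length in s.
#' @param noisy for the switching kinds, draw Poisson counts around the
#'   state level instead of deterministic counts.
#' @return An [activity_trace()].
#' @export
fixture_generator <- function(kind = c("poisson", "telegraph", "square_wave"),
                              seed = 1L, N = 100, rate = 10,
                              levels = c(2, 40), switch_rate = 1, period = 2,
                              dt = 1e-3, duration = 100, noisy = FALSE) {
  kind <- match.arg(kind)
  n <- as.integer(round(duration / dt))
  with_seed(seed, {
    if (kind == "poisson") {
      counts <- matrix(pmin(stats::rpois(n, N * rate * dt), N), ncol = 1)
      return(activity_trace(dt, counts, N))
    }
    tt <- (seq_len(n) - 1L) * dt
    if (kind == "telegraph") {
      durs <- stats::rexp(ceiling(4 * duration * switch_rate) + 20,
                          rate = switch_rate)
      edges <- cumsum(durs)
      state <- (findInterval(tt, edges) %% 2L) == 0L
    } else {
      state <- (tt %% period) < period / 2
    }
    lv1 <- ifelse(state, levels[2], levels[1])
    lv2 <- ifelse(state, levels[1], levels[2])
    mk <- function(lv) {
      if (noisy) pmin(stats::rpois(n, N * lv * dt), N)
      else pmin(round(N * lv * dt), N)
    }
    activity_trace(dt, cbind(mk(lv1), mk(lv2)), c(N, N))
  })
}
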