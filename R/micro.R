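micro_prepare <- function(spec, settings) {
  M <- n_populations(spec)
  dt <- settings$dt
  out <- vector("list", M)
  for (a in seq_len(M)) {
    pop <- spec$populations[[a]]
    k_ref <- max(1L, as.integer(round(pop$t_ref / dt)))
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
    nth <- n_components(pop$theta)
    neta <- if (is_empty_kernel(pop$eta)) 0L else length(pop$eta$J)
    out[[a]] <- list(
      N = pop$N, k_ref = k_ref,
      variant = if (pop$model_variant == "GIF") 0L else 1L,
      u_th = pop$u_th, u_r = pop$u_r, u_rest = pop$u_rest,
      c = pop$c, delta_u = pop$delta_u, em = em,
      coefA = pop$tau_m * (1 - em),
      th_jump = if (nth) pop$theta$J / pop$theta$tau else numeric(0),
      th_decay = if (nth) exp(-dt / pop$theta$tau) else numeric(0),
      eta_jump = if (neta) pop$eta$J / pop$eta$tau else numeric(0),
      eta_decay = if (neta) exp(-dt / pop$eta$tau) else numeric(0),
      es = es, coefY = coefY,
      delay_steps = pmax(1L, as.integer(round(spec$delay[a, ] / dt))),
      w = spec$w[a, ])
  }
  out
}

# Convert in-degree lists to postsynaptic (out) lists in CSR form, 0-based,
# one block per source population.
conn_to_outlists <- function(conn, M) {
  out <- vector("list", M)
  for (b in seq_len(M)) {
    pops <- integer(0); idxs <- integer(0); src <- integer(0)
    for (a in seq_len(M)) {
      mat <- conn$pre[[a]][[b]]
      if (nrow(mat) == 0L) next
      n_syn <- length(mat)
      src <- c(src, as.integer(mat))                # presynaptic (source) id
      pops <- c(pops, rep.int(a - 1L, n_syn))       # target population
      idxs <- c(idxs, rep(seq_len(ncol(mat)) - 1L, each = nrow(mat)))
    }
    o <- order(src)
    src <- src[o]; pops <- pops[o]; idxs <- idxs[o]
    start <- c(0L, cumsum(tabulate(src, nbins = conn$N[b])))
    out[[b]] <- list(start = start, pop = pops, idx = idxs)
  }
  out
}

#' Simulate the microscopic spiking network
#'
#' Neuron-by-neuron simulation of the GIF (or GLM) network with fixed
#' in-degree random connectivity: exact exponential integration of the
#' membrane potential and threshold states between spikes, trapezoidal
#' averaging of the hazard over each step, one Bernoulli draw per
#' non-refractory neuron per step. This is the reference against which
#' the mesoscopic integrator is validated.
#'
#' @param spec a [network_spec()].
#' @param settings a [sim_settings()]; `settings$warmup` adds an
#'   unrecorded (stochastic) leading segment.
#' @param conn optional prebuilt [build_connectivity()] object; built
#'   from `settings$seed` otherwise.
#' @param validate check the time step first.
#' @return An [activity_trace()]; carries a raster data frame
#'   (`time_s`, `population`, `neuron`) if `settings$record_raster`.
#' @examples
#' pre <- preset_uncoupled_lif(mu = 30, N = 50)
#' tr <- run_micro(pre$spec, sim_settings(dt = 5e-4, duration = 0.5, seed = 1))
#' colMeans(tr$activity)
#' @export
run_micro <- function(spec, settings, conn = NULL, validate = TRUE) {
  stopifnot(inherits(spec, "network_spec"), inherits(settings, "sim_settings"))
  if (identical(settings$init, "stationary")) {
    stop("init = \"stationary\" is only available for run_meso(); use \"free\"")
  }
  if (validate) validate_dt(spec, settings$dt, probe = FALSE)
  M <- n_populations(spec)
  n_steps <- as.integer(round(settings$duration / settings$dt))
  n_warm <- as.integer(round(settings$warmup / settings$dt))
  if (n_steps == 0L) {
    return(activity_trace(settings$dt, matrix(0, 0, M), pop_sizes(spec)))
  }
  if (is.null(conn)) conn <- build_connectivity(spec, seed = settings$seed)
  pops <- micro_prepare(spec, settings)
  outl <- conn_to_outlists(conn, M)
  stim <- stimulus_matrix(spec, settings, n_steps, n_warm)
  res <- with_seed(settings$seed,
    micro_run_cpp(pops, outl, stim, n_steps, n_warm, settings$dt,
                  settings$record_raster, identical(settings$init, "free")))
  raster <- NULL
  if (settings$record_raster) {
    raster <- data.frame(time_s = res$raster_bin * settings$dt,
                         population = res$raster_pop,
                         neuron = res$raster_idx)
  }
  nm <- vapply(spec$populations, function(q) q$name %||% "", "")
  activity_trace(settings$dt, res$counts, pop_sizes(spec), raster = raster,
                 pop_names = if (all(nzchar(nm))) nm else NULL)
}

#' Simulate the binomial survival-number process of one population
#'
#' The intermediate level between the microscopic network and the
#' mesoscopic equations: the refractory distribution \eqn{m(t_l, t_k)}
#' (number of neurons whose last spike lies in bin \eqn{t_k} that have
#' not fired again by \eqn{t_l}) is evolved explicitly. Each refractory
#' state loses a binomial number of neurons
#' \eqn{X_{lk} \sim B(m(t_l,t_k), P_\lambda(t_l|t_k))} per step and the
#' bin activity is \eqn{\Delta n(t_l) = \sum_k X_{lk}}. Neuron numbers
#' are conserved exactly; a violation aborts the run. The hazards use the
#' mean-field membrane and quasi-renewal threshold, so for a single
#' population this process and [run_meso()] describe the same system at
#' different levels of aggregation.
#'
#' @param spec a [network_spec()] with exactly one population (the
#'   population may be self-coupled through `p`, `w`).
#' @param settings a [sim_settings()].
#' @param validate check the time step first.
#' @return An [activity_trace()] with an extra field `conserved_total`,
#'   the per-step total neuron count (always `N`).
#' @export
run_density_micro <- function(spec, settings, validate = TRUE) {
  stopifnot(inherits(spec, "network_spec"), inherits(settings, "sim_settings"))
  if (identical(settings$init, "stationary")) {
    stop("init = \"stationary\" is only available for run_meso(); use \"free\"")
  }
  if (n_populations(spec) != 1L) {
    stop("run_density_micro expects a single-population network")
  }
  if (validate) validate_dt(spec, settings$dt, probe = FALSE)
  n_steps <- as.integer(round(settings$duration / settings$dt))
  if (n_steps == 0L) {
    return(activity_trace(settings$dt, matrix(0, 0, 1), pop_sizes(spec)))
  }
  pops <- meso_prepare(spec, settings)
  stim <- stimulus_matrix(spec, settings, n_steps, 0L)
  res <- with_seed(settings$seed,
    density_run_cpp(pops[[1]], stim[, 1], n_steps, settings$dt,
                    identical(settings$init, "free")))
  tr <- activity_trace(settings$dt, res$counts, pop_sizes(spec))
  tr$conserved_total <- res$total
  tr
}
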