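kernel_to_list <- function(kernel) {
  if (is_empty_kernel(kernel)) {
    return(list(t_ref = kernel$t_ref, components = list()))
  }
  list(t_ref = kernel$t_ref,
       components = lapply(seq_along(kernel$J), function(l) {
         list(J = kernel$J[l], tau = kernel$tau[l])
       }))
}

kernel_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  J <- vapply(x$components, function(cmp) cmp$J, 0)
  tau <- vapply(x$components, function(cmp) cmp$tau, 0)
  adaptation_kernel(J = J, tau = tau, t_ref = x$t_ref)
}

pop_to_list <- function(pop) {
  out <- list(name = pop$name, N = pop$N, tau_m = pop$tau_m,
              t_ref = pop$t_ref, u_th = pop$u_th, u_r = pop$u_r,
              u_rest = pop$u_rest, c = pop$c, delta_u = pop$delta_u,
              model_variant = pop$model_variant,
              theta = kernel_to_list(pop$theta))
  if (!is_empty_kernel(pop$eta)) out$eta <- kernel_to_list(pop$eta)
  out
}

pop_from_list <- function(x) {
  population_params(N = x$N, tau_m = x$tau_m, t_ref = x$t_ref,
                    u_th = x$u_th, u_r = x$u_r, u_rest = x$u_rest,
                    c = x$c, delta_u = x$delta_u,
                    theta = kernel_from_list(x$theta),
                    eta = kernel_from_list(x$eta),
                    model_variant = x$model_variant, name = x$name)
}

matrix_to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) {
  as.numeric(m[i, ])
})

rows_to_matrix <- function(x) do.call(rbind, lapply(x, as.numeric))

stim_to_list <- function(stim) {
  if (is.null(stim) || nrow(stim) == 0L) return(list())
  lapply(seq_len(nrow(stim)), function(i) {
    list(t_on = stim$t_on[i], t_off = stim$t_off[i],
         amplitude = stim$amplitude[i])
  })
}

stim_from_list <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  step_stimulus(t_on = vapply(x, function(s) s$t_on, 0),
                t_off = vapply(x, function(s) s$t_off, 0),
                amplitude = vapply(x, function(s) s$amplitude, 0))
}

#' Write and read model configurations
#'
#' Serializes a preset (network specification plus simulation settings)
#' to a hierarchical YAML file and reads it back losslessly. Kernel
#' components are stored as `(J, tau)` pairs in mV s and s.
#'
#' @param preset a `preset` (see e.g. [preset_uncoupled_lif()]) or a
#'   list with elements `spec` and `settings`.
#' @param path file path (YAML text).
#' @return `read_config()` returns a `preset`.
#' @export
write_config <- function(preset, path) {
  spec <- preset$spec
  cfg <- list(
    name = preset$name %||% "custom",
    description = preset$description %||% "",
    populations = lapply(spec$populations, pop_to_list),
    connectivity = list(p = matrix_to_rows(spec$p),
                        w = matrix_to_rows(spec$w),
                        delay = matrix_to_rows(spec$delay),
                        tau_s = as.numeric(spec$tau_s)),
    stimulus = lapply(spec$stimulus, stim_to_list),
    settings = unclass(preset$settings))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pops <- lapply(cfg$populations, pop_from_list)
  spec <- network_spec(
    populations = pops,
    p = rows_to_matrix(cfg$connectivity$p),
    w = rows_to_matrix(cfg$connectivity$w),
    delay = rows_to_matrix(cfg$connectivity$delay),
    tau_s = as.numeric(cfg$connectivity$tau_s),
    stimulus = lapply(cfg$stimulus, stim_from_list))
  s <- cfg$settings
  settings <- sim_settings(dt = s$dt, duration = s$duration, seed = s$seed,
                           history_T = if (identical(s$history_T, "auto"))
                             "auto" else as.numeric(unlist(s$history_T)),
                           sampling = s$sampling,
                           init = s$init %||% "synchronized",
                           record_expected = s$record_expected,
                           record_raster = s$record_raster,
                           warmup = s$warmup, tol_theta = s$tol_theta)
  new_preset(cfg$name, spec, settings, cfg$description)
}
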