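# Small model builders shared across test files.

lif_population <- function(N = 100, mu = 20, ...) {
  population_params(N = N, u_rest = mu, ...)
}

uncoupled_spec <- function(N = 100, mu = 20, ...) {
  network_spec(list(lif_population(N = N, mu = mu, ...)),
               p = matrix(0, 1, 1), w = matrix(0, 1, 1),
               delay = 0.001, tau_s = 0.003)
}

# single self-coupled population (mean-field coupling J = p*N*w)
selfcoupled_spec <- function(N = 100, mu = 20, w = 0.01, p = 1,
                             tau_s = 0.003, ...) {
  network_spec(list(lif_population(N = N, mu = mu, ...)),
               p = matrix(p, 1, 1), w = matrix(w, 1, 1),
               delay = 0.001, tau_s = tau_s)
}

# absolute-refractory Poisson population: GLM variant with empty kernels
poisson_refractory_spec <- function(N = 400, mu = 16, w = 0, t_ref = 0.004) {
  pop <- population_params(N = N, u_rest = mu, t_ref = t_ref,
                           theta = adaptation_kernel(t_ref = t_ref),
                           model_variant = "GLM")
  network_spec(list(pop), p = matrix(1, 1, 1), w = matrix(w, 1, 1),
               delay = 0.001, tau_s = 0.003)
}
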