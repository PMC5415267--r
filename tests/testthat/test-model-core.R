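test_that("spike-triggered kernel evaluates piecewise as defined", {
  k <- adaptation_kernel(J = c(1.5, 1.5), tau = c(0.01, 1), t_ref = 0.004)
  expect_equal(theta_kernel_eval(k, c(-1, 0)), c(0, 0))
  expect_equal(theta_kernel_eval(k, 0.002), Inf)
  tt <- c(0.004, 0.05, 1)
  expect_equal(theta_kernel_eval(k, tt),
               (1.5 / 0.01) * exp(-tt / 0.01) + (1.5 / 1) * exp(-tt / 1))
  # empty kernel: zero beyond the dead time
  k0 <- adaptation_kernel(t_ref = 0.004)
  expect_equal(theta_kernel_eval(k0, c(0.004, 1)), c(0, 0))
  expect_equal(theta_kernel_eval(k0, 0.001), Inf)
})

test_that("kernel constructor validates its arguments", {
  expect_error(adaptation_kernel(J = 1, tau = c(1, 2)), "same length")
  expect_error(adaptation_kernel(J = 1, tau = -1), "tau")
  expect_error(adaptation_kernel(t_ref = 0), "t_ref")
})

test_that("quasi-renewal kernel saturates at delta_u and is bounded by theta", {
  k <- adaptation_kernel(J = 0.5, tau = 0.2, t_ref = 0.004)
  du <- 2
  # closed-form check points
  expect_equal(quasi_renewal_kernel(adaptation_kernel(t_ref = 1e-4), 0.5, du),
               0)                                    # theta = 0
  expect_equal(quasi_renewal_kernel(k, 0.002, du), du)  # theta = Inf
  # theta(t*) = delta_u  =>  qr = delta_u (1 - 1/e)
  tstar <- 0.2 * log((0.5 / 0.2) / du)
  expect_equal(quasi_renewal_kernel(k, tstar, du), du * (1 - exp(-1)),
               tolerance = 1e-12)
  # bound and monotonicity over a grid
  tt <- seq(0.004, 2, length.out = 200)
  th <- theta_kernel_eval(k, tt)
  qr <- quasi_renewal_kernel(k, tt, du)
  expect_true(all(qr <= pmin(th, du) + 1e-12))
  expect_true(all(diff(qr) <= 1e-12)) # decreasing where theta decreases
})

test_that("escape rate follows the exponential link function", {
  expect_equal(escape_rate(15, 15, c = 10, delta_u = 2), 10)
  expect_equal(escape_rate(17, 15, c = 10, delta_u = 2), 10 * exp(1))
  expect_equal(escape_rate(0, Inf, c = 10, delta_u = 2), 0) # refractory
  # e-fold scaling property: lambda(u + delta_u) = e * lambda(u)
  u <- seq(-10, 20, by = 2.5)
  expect_equal(escape_rate(u + 3, 15, 10, 3), exp(1) * escape_rate(u, 15, 10, 3))
  # monotone in u, decreasing in threshold
  expect_true(all(diff(escape_rate(u, 15, 10, 2)) > 0))
  expect_true(escape_rate(10, 12, 10, 2) > escape_rate(10, 14, 10, 2))
  # exponent clamp keeps the rate finite
  expect_true(is.finite(escape_rate(1e4, 0, 10, 2)))
  expect_error(escape_rate(NaN, 15, 10, 2), "non-finite")
  expect_error(escape_rate(1, 15, 10, -1), "delta_u")
})

test_that("explicit-history length covers refractoriness and kernel decay", {
  # no adaptation: n_rel * max(t_ref, tau_m)
  expect_equal(choose_history_length(population_params(N = 10)), 0.1)
  expect_equal(choose_history_length(
    population_params(N = 10, tau_m = 0.001, t_ref = 0.004)), 0.02)
  # slow weak kernel: T solves (J/tau) e^{-T/tau} = tol * delta_u
  pop <- population_params(N = 10, delta_u = 2.5,
                           theta = adaptation_kernel(J = 0.1, tau = 1,
                                                     t_ref = 0.004))
  expect_equal(choose_history_length(pop), log(4), tolerance = 1e-6)
  # grid alignment rounds up
  expect_equal(choose_history_length(pop, dt = 5e-4) %% 5e-4, 0)
  expect_gte(choose_history_length(pop, dt = 5e-4), log(4) - 1e-9)
  # invariant under component reordering
  two <- function(Js, taus) population_params(N = 10, delta_u = 2,
    theta = adaptation_kernel(J = Js, tau = taus, t_ref = 0.004))
  expect_equal(choose_history_length(two(c(0.3, 1.5), c(0.5, 0.01))),
               choose_history_length(two(c(1.5, 0.3), c(0.01, 0.5))))
  expect_error(choose_history_length(pop, tol_theta = 0), "tol_theta")
  expect_error(choose_history_length(pop, tol_theta = 1), "tol_theta")
})

test_that("time-step validation enforces refractory and delay bounds", {
  spec <- uncoupled_spec(N = 10)
  res <- validate_dt(spec, 5e-4, probe = FALSE)
  expect_true(res$pass_t_ref && res$pass_delay)
  expect_error(validate_dt(spec, 5e-3, probe = FALSE), "refractory")
  expect_error(validate_dt(spec, 2e-3, probe = FALSE), "delay")
  # probe runs and reports a ratio
  res2 <- validate_dt(spec, 5e-4, probe = TRUE)
  expect_true(is.finite(res2$trapezoid_ratio))
})

test_that("population and network constructors enforce invariants", {
  expect_error(population_params(N = 0), "N")
  expect_error(population_params(N = 10, delta_u = 0), "delta_u")
  expect_error(population_params(N = 10,
    eta = adaptation_kernel(J = 1, tau = 1, t_ref = 0.004)), "eta")
  # GLM may carry eta
  pop <- population_params(N = 10, model_variant = "GLM",
                           eta = adaptation_kernel(J = -1, tau = 0.02,
                                                   t_ref = 0.004))
  expect_s3_class(pop, "population_params")
  expect_error(network_spec(list(lif_population()), p = matrix(2, 1, 1)),
               "probabilities")
  expect_error(network_spec(list(lif_population()), delay = 0), "delay")
})
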