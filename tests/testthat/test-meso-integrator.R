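test_that("free potential is a fixed point without input and relaxes to mu", {
  # no drive, no firing: h stays at u_rest
  spec <- uncoupled_spec(N = 50, mu = 5, c = 0)
  st <- sim_settings(dt = 5e-4, duration = 0.3, seed = 1,
                     sampling = "expected", init = "free")
  tr <- run_meso(spec, st, record_free_potential = TRUE)
  expect_equal(max(abs(tr$free_potential - 5)), 0)
  # constant external drive: exponential relaxation with tau_m
  spec2 <- uncoupled_spec(N = 50, mu = 5, c = 0)
  spec2$stimulus[[1]] <- step_stimulus(0, 1e9, 10)
  tr2 <- run_meso(spec2, st, record_free_potential = TRUE)
  tt <- tr2$time + st$dt # h is recorded at the end of each step
  expect_equal(tr2$free_potential[, 1], 5 + 10 * (1 - exp(-tt / 0.02)),
               tolerance = 1e-10)
})

test_that("one-step synaptic integration matches a dense ODE solution", {
  skip_if_not_installed("deSolve")
  # population 2 (silent, c = 0) is driven by the deterministic expected
  # activity of population 1; its free potential must solve
  #   tau_m h' = -h + u_rest + tau_m J y,  tau_s y' = -y + A1(t - delta)
  # exactly, because inputs are piecewise constant over the steps.
  dt <- 5e-4
  pop1 <- population_params(N = 200, u_rest = 25, name = "src")
  pop2 <- population_params(N = 10, u_rest = 3, c = 0, tau_m = 0.02,
                            name = "tgt")
  spec <- network_spec(list(pop1, pop2),
                       p = matrix(c(0, 1, 0, 0), 2, 2),
                       w = matrix(c(0, 0.05, 0, 0), 2, 2),
                       delay = 0.001, tau_s = c(0.003, 0.006))
  st <- sim_settings(dt = dt, duration = 0.2, seed = 2,
                     sampling = "expected")
  tr <- run_meso(spec, st, record_free_potential = TRUE)
  J <- 200 * 0.05
  A1 <- tr$activity[, 1]
  dstep <- round(0.001 / dt)
  n <- nrow(tr$counts)
  # delayed activity per bin; synchronization pulse 1/dt in bin -1
  A_d <- vapply(seq_len(n) - 1L, function(l) {
    k <- l - dstep
    if (k >= 0) A1[k + 1] else if (k == -1) 1 / dt else 0
  }, 0)
  # integrate bin by bin with the forcing frozen (it is piecewise
  # constant), so the ODE is smooth within each integration window
  state <- c(h = 3, y = 0)
  h_dense <- numeric(n)
  for (l in seq_len(n)) {
    rhs <- function(t, y, parms) {
      list(c((-(y[1] - 3) + 0.02 * J * y[2]) / 0.02,
             (-y[2] + A_d[l]) / 0.003))
    }
    sol <- deSolve::rk4(state, times = seq(0, dt, length.out = 9), rhs,
                        parms = NULL)
    state <- sol[nrow(sol), c("h", "y")]
    h_dense[l] <- state["h"]
  }
  rel <- abs(tr$free_potential[, 2] - h_dense) / max(abs(h_dense))
  expect_lt(max(rel), 1e-8)
})

test_that("deterministic mode is reproducible and noise-free", {
  pre <- preset_ei_network(N = 50, p = 1)
  st <- sim_settings(dt = 5e-4, duration = 1, seed = 1,
                     sampling = "expected", record_expected = TRUE)
  t1 <- run_meso(pre$spec, st)
  st$seed <- 999 # the seed must not matter without sampling
  t2 <- run_meso(pre$spec, st)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$expected, t2$expected)
})

test_that("compiled integrator and pure-R reference produce identical runs", {
  pre <- preset_ei_network(N = 50, p = 1)
  st <- sim_settings(dt = 5e-4, duration = 0.4, seed = 7,
                     record_expected = TRUE)
  a <- run_meso(pre$spec, st)
  b <- run_meso_reference(pre$spec, st)
  expect_identical(a$counts, b$counts) # same draws, same trajectory
  expect_lt(max(abs(a$expected - b$expected)), 1e-9)
  # free start as well
  st2 <- sim_settings(dt = 5e-4, duration = 0.4, seed = 8, init = "free",
                      record_expected = TRUE)
  a2 <- run_meso(pre$spec, st2)
  b2 <- run_meso_reference(pre$spec, st2)
  expect_identical(a2$counts, b2$counts)
})

test_that("iterative threshold sweep equals brute-force kernel summation", {
  # adapting population with a short kernel so the history stays small
  pop <- population_params(N = 80, u_rest = 22, delta_u = 2,
                           theta = adaptation_kernel(J = c(0.05, -0.01),
                                                     tau = c(0.05, 0.02),
                                                     t_ref = 0.004))
  spec <- network_spec(list(pop), p = matrix(1, 1, 1),
                       w = matrix(-0.01, 1, 1), delay = 0.001,
                       tau_s = 0.003)
  st <- sim_settings(dt = 5e-4, duration = 0.5, seed = 3,
                     record_expected = TRUE)
  sweep <- run_meso_reference(spec, st, brute_force = FALSE)
  brute <- run_meso_reference(spec, st, brute_force = TRUE)
  expect_identical(sweep$counts, brute$counts)
  expect_lt(max(abs(sweep$expected - brute$expected)), 1e-10)
})

test_that("general integrator reduces exactly to the closed refractory-Poisson equation", {
  # lambda(t|t_hat) = f(h(t)) Theta(t - t_hat - t_ref): the mesoscopic
  # equation closes as A_bar = f(h) (1 - int_{t-t_ref}^t A_N); the
  # general machinery must reproduce an independent implementation of
  # that equation to machine precision, including the self-coupled case.
  for (cfg in list(list(w = 0, mu = 16, init = "synchronized"),
                   list(w = -0.02, mu = 18, init = "synchronized"),
                   list(w = 0.005, mu = 15, init = "free"))) {
    spec <- poisson_refractory_spec(N = 400, mu = cfg$mu, w = cfg$w)
    st <- sim_settings(dt = 5e-4, duration = 3, seed = 11, init = cfg$init,
                       record_expected = TRUE)
    tr <- run_meso(spec, st)
    oracle <- wilson_cowan_expected(spec, tr, st)
    rel <- abs(tr$expected[, 1] - oracle) / pmax(abs(oracle), 1e-9)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("adaptation level of free neurons tracks the stationary activity", {
  # at a stationary activity A*, g -> A* and the free threshold sits at
  # u_th + sum_l J_l exp(-T/tau_l) A*
  pop <- population_params(N = 100, u_rest = 22, delta_u = 2,
                           theta = adaptation_kernel(J = 0.02, tau = 0.2,
                                                     t_ref = 0.004))
  spec <- network_spec(list(pop), p = matrix(0, 1, 1), w = matrix(0, 1, 1),
                       delay = 0.001, tau_s = 0.003)
  st <- sim_settings(dt = 2e-4, duration = 4, seed = 5,
                     sampling = "expected", init = "free",
                     record_expected = TRUE)
  tr <- run_meso(spec, st, record_free_potential = TRUE)
  n <- nrow(tr$counts)
  A_star <- mean(tr$expected[(n - 500):n, 1])
  T_hist <- choose_history_length(pop, dt = st$dt)
  th_pred <- pop$u_th + 0.02 * exp(-T_hist / 0.2) * A_star
  expect_equal(mean(tr$free_threshold[(n - 500):n, 1]), th_pred,
               tolerance = 0.001)
})

test_that("stationary initialization starts at the mean-field fixed point", {
  pre <- preset_ei_network(N = 500, p = 0.2, C = 100, w = 0.1)
  st <- sim_settings(dt = 5e-4, duration = 1, seed = 9,
                     sampling = "expected", init = "stationary",
                     record_expected = TRUE)
  r0 <- stationary_rates(pre$spec, st)
  tr <- run_meso(pre$spec, st)
  # the deterministic dynamics should stay at the fixed point
  drift <- abs(sweep(tr$expected, 2, r0, "-")) / rep(r0, each = nrow(tr$expected))
  expect_lt(max(drift), 0.02)
})

test_that("sampled spike counts respect the population-size bound", {
  pre <- preset_ei_network(N = 50, p = 1)
  st <- sim_settings(dt = 5e-4, duration = 3, seed = 12, init = "free")
  tr <- run_meso(pre$spec, st)
  expect_true(all(tr$counts >= 0))
  expect_true(all(sweep(tr$counts, 2, tr$N, "<=")))
  # poisson and gaussian sampling modes run and respect the bound too
  for (mode in c("poisson", "gaussian")) {
    st2 <- sim_settings(dt = 5e-4, duration = 0.5, seed = 13,
                        sampling = mode, init = "free")
    tr2 <- run_meso(pre$spec, st2)
    expect_true(all(tr2$counts >= 0 & sweep(tr2$counts, 2, tr2$N, "<=")))
  }
})

test_that("warmup discards the transient from the recorded trace", {
  spec <- uncoupled_spec(N = 100, mu = 24)
  st <- sim_settings(dt = 5e-4, duration = 2, seed = 4, warmup = 1)
  tr <- run_meso(spec, st)
  expect_equal(nrow(tr$counts), 4000L)
  # the synchronization transient (rate ringing) must not be visible
  r_first <- mean(tr$activity[1:500, 1])
  r_last <- mean(tr$activity[3501:4000, 1])
  expect_equal(r_first, r_last, tolerance = 0.15)
})
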