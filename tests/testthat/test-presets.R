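test_that("uncoupled LIF preset uses the default single-neuron parameters", {
  pre <- preset_uncoupled_lif(mu = 30, N = 500)
  pop <- pre$spec$populations[[1]]
  expect_equal(pop$N, 500L)
  expect_equal(pop$u_th, 15)
  expect_equal(pop$u_r, 0)
  expect_equal(pop$u_rest, 30)
  expect_equal(pop$tau_m, 0.02)
  expect_equal(pop$t_ref, 0.004)
  expect_equal(pop$c, 10)
  expect_equal(pop$delta_u, 2)
  expect_equal(pre$spec$p[1, 1], 0)
  expect_equal(n_components(pop$theta), 0L)
  # step variant: baseline 15 mV, step to mu
  pre2 <- preset_uncoupled_lif(mu = 30, step_time = 0.5)
  expect_equal(pre2$spec$populations[[1]]$u_rest, 15)
  expect_equal(pre2$spec$stimulus[[1]]$amplitude, 15)
})

test_that("adapting and bursty presets carry the stated kernels", {
  ad <- preset_adapting("adapting")
  pop <- ad$spec$populations[[1]]
  expect_equal(pop$u_th, 10)
  expect_equal(pop$u_r, 25)
  expect_equal(pop$theta$J, c(1.5, 1.5))
  expect_equal(pop$theta$tau, c(0.01, 1))
  # kernel value just after the dead time
  expect_equal(theta_kernel_eval(pop$theta, 0.004),
               (1.5 / 0.01) * exp(-0.004 / 0.01) + 1.5 * exp(-0.004))
  bu <- preset_adapting("bursty")
  bpop <- bu$spec$populations[[1]]
  expect_equal(bpop$tau_m, 0.01)
  expect_equal(bpop$u_r, 0)
  expect_equal(bpop$u_rest, 20)
  expect_true(any(bpop$theta$J < 0)) # facilitation component
  expect_error(preset_adapting("oscillating"))
})

test_that("E-I preset keeps the total coupling constant under rescaling", {
  p200 <- preset_ei_network(N = 1000, C = 200)
  expect_equal(p200$spec$w[1, 1], 0.3)
  expect_equal(p200$spec$w[1, 2], -1.5)
  expect_equal(pop_sizes(p200$spec), c(800L, 200L))
  # halving N at fixed C leaves J = p N w unchanged
  p50 <- preset_ei_network(N = 50, p = 1)
  J1 <- p200$spec$p * matrix(pop_sizes(p200$spec), 2, 2, TRUE) * p200$spec$w
  J2 <- p50$spec$p * matrix(pop_sizes(p50$spec), 2, 2, TRUE) * p50$spec$w
  expect_equal(J1, J2, ignore_attr = TRUE)
  expect_equal(p50$spec$p[1, 1], 1)
  expect_error(preset_ei_network(N = 33), "divisible")
})

test_that("bistable preset matches the stated weights and is E1/E2 symmetric", {
  pre <- preset_bistable(adaptation = FALSE)
  expect_equal(pop_sizes(pre$spec), c(400L, 400L, 200L))
  expect_equal(pre$spec$w[1, 1], 0.0624)
  expect_equal(pre$spec$w[1, 3], -0.2496)
  expect_equal(n_components(pre$spec$populations[[1]]$theta), 0L)
  prea <- preset_bistable(adaptation = TRUE)
  expect_equal(prea$spec$w[1, 1], 0.096)
  expect_equal(prea$spec$w[1, 3], -0.384)
  expect_equal(prea$spec$populations[[1]]$theta$J, 0.1)
  expect_equal(prea$spec$populations[[1]]$theta$tau, 1)
  expect_equal(prea$spec$populations[[1]]$u_rest, 36.5)
  # symmetry under exchange of the two excitatory populations
  perm <- c(2, 1, 3)
  for (pre_k in list(pre, prea)) {
    expect_equal(pre_k$spec$p[perm, perm], pre_k$spec$p, ignore_attr = TRUE)
    expect_equal(pre_k$spec$w[perm, perm], pre_k$spec$w, ignore_attr = TRUE)
  }
})

test_that("cortical-column preset reproduces the published table", {
  pre <- preset_cortical_column(with_adaptation = FALSE,
                                with_stimulus = TRUE)
  spec <- pre$spec
  expect_equal(pop_sizes(spec),
               c(20683L, 5834L, 21915L, 5479L, 4850L, 1065L, 14395L, 2948L))
  expect_equal(spec$p["L2/3e", "L2/3i"], 0.1689)
  expect_equal(spec$p["L6i", "L6e"], 0.0658)
  expect_equal(spec$w["L2/3e", "L4e"], 0.351)
  expect_equal(spec$w["L4e", "L4e"], 0.176)
  expect_equal(spec$w["L5i", "L2/3i"], -0.702)
  expect_equal(unique(spec$tau_s), 5e-4)
  expect_equal(unique(as.vector(spec$delay)), 1.5e-3)
  pops <- spec$populations
  expect_equal(pops[[3]]$u_rest, 30.805)
  expect_equal(pops[[1]]$delta_u, 5)
  expect_equal(pops[[1]]$t_ref, 0.002)
  expect_equal(pops[[1]]$tau_m, 0.01)
  # thalamic step on L4e
  expect_equal(spec$stimulus[[3]],
               step_stimulus(0.06, 0.09, 19))
  expect_equal(spec$stimulus[[4]]$amplitude, 11.964)
  expect_null(spec$stimulus[[1]])
  # adaptation variant: raised resting potentials, kernels on e-pops only
  prea <- preset_cortical_column(with_adaptation = TRUE)
  expect_equal(prea$spec$populations[[5]]$u_rest, 37.578)
  expect_equal(prea$spec$populations[[2]]$u_rest, 20.362)
  expect_equal(n_components(prea$spec$populations[[1]]$theta), 1L)
  expect_equal(n_components(prea$spec$populations[[2]]$theta), 0L)
  expect_equal(prea$target_rates,
               c(0.974, 2.861, 4.673, 5.65, 8.141, 9.013, 0.988, 7.53))
})

test_that("every preset passes the time-step validation", {
  presets <- list(preset_uncoupled_lif(), preset_adapting("adapting"),
                  preset_adapting("bursty"), preset_ei_network(N = 50, p = 1),
                  preset_bistable(FALSE), preset_bistable(TRUE),
                  preset_cortical_column(TRUE, TRUE))
  for (pre in presets) {
    res <- validate_dt(pre$spec, pre$settings$dt, probe = FALSE)
    expect_true(res$pass_t_ref && res$pass_delay)
  }
})

test_that("configurations round-trip losslessly through the config file", {
  pre <- preset_cortical_column(with_adaptation = TRUE, with_stimulus = TRUE)
  pre$settings$init <- "free"
  pre$settings$warmup <- 0.5
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(pre, path)
  back <- read_config(path)
  expect_equal(back$spec$p, pre$spec$p, ignore_attr = TRUE)
  expect_equal(back$spec$w, pre$spec$w, ignore_attr = TRUE)
  expect_equal(back$spec$delay, pre$spec$delay, ignore_attr = TRUE)
  expect_equal(back$spec$tau_s, pre$spec$tau_s)
  for (a in seq_along(pre$spec$populations)) {
    pa <- pre$spec$populations[[a]]; pb <- back$spec$populations[[a]]
    for (f in c("N", "tau_m", "t_ref", "u_th", "u_r", "u_rest", "c",
                "delta_u", "model_variant", "name")) {
      expect_identical(pb[[f]], pa[[f]])
    }
    expect_equal(pb$theta$J, pa$theta$J)
    expect_equal(pb$theta$tau, pa$theta$tau)
  }
  expect_equal(back$spec$stimulus[[3]], pre$spec$stimulus[[3]])
  expect_equal(unclass(back$settings), unclass(pre$settings))
  # an adapting single-population preset round-trips too
  pre2 <- preset_adapting("bursty")
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(pre2, path2)
  back2 <- read_config(path2)
  expect_equal(back2$spec$populations[[1]]$theta$J,
               pre2$spec$populations[[1]]$theta$J)
})

test_that("fixtures are deterministic and match their nominal statistics", {
  f1 <- fixture_generator("poisson", seed = 7, N = 100, rate = 10,
                          duration = 100)
  f2 <- fixture_generator("poisson", seed = 7, N = 100, rate = 10,
                          duration = 100)
  expect_identical(f1$counts, f2$counts)
  expect_equal(mean(f1$activity), 10, tolerance = 0.02)
  f3 <- fixture_generator("poisson", seed = 8, N = 100, rate = 10,
                          duration = 100)
  expect_false(identical(f1$counts, f3$counts))
})

test_that("activity traces round-trip through delimited text", {
  tr <- fixture_generator("poisson", seed = 2, N = 50, rate = 5,
                          duration = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity(tr, path, seed = 2)
  back <- read_activity(path)
  expect_equal(back$dt, tr$dt)
  expect_equal(back$N, tr$N)
  expect_equal(unname(back$counts), unname(tr$counts))
})
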