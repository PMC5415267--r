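test_that("power spectrum of a constant trace vanishes", {
  tr <- activity_trace(1e-3, matrix(5L, 2000, 1), N = 100)
  sp <- power_spectrum(tr, segment_length = 0.5)
  expect_true(all(sp$power < 1e-18))
  expect_equal(sp$n_segments, 4L)
  expect_equal(sp$frequencies[1], 2)
})

test_that("Poisson population has a flat spectrum at r/N", {
  tr <- fixture_generator("poisson", seed = 5, N = 100, rate = 10,
                          dt = 1e-3, duration = 200)
  sp <- power_spectrum(tr, segment_length = 1)
  expect_equal(mean(sp$power), 10 / 100, tolerance = 0.03)
  # flat: low- and high-frequency halves agree
  half <- length(sp$frequencies) %/% 2
  expect_equal(mean(sp$power[1:half, 1]),
               mean(sp$power[(half + 1):(2 * half), 1]), tolerance = 0.05)
})

test_that("spectrum integrates to the variance (Parseval)", {
  tr <- fixture_generator("poisson", seed = 8, N = 50, rate = 20,
                          dt = 1e-3, duration = 50)
  sp <- power_spectrum(tr, segment_length = 1)
  nlen <- round(sp$segment_length / tr$dt)
  # two-sided spectrum: DC excluded, Nyquist counted once
  integral <- (2 * sum(sp$power[-length(sp$frequencies), 1]) +
                 sp$power[length(sp$frequencies), 1]) / sp$segment_length
  x <- tr$activity[seq_len(sp$n_segments * nlen), 1]
  v <- mean(apply(matrix(x, nlen), 2, stats::var) * (nlen - 1) / nlen)
  expect_equal(integral, v, tolerance = 0.01)
})

test_that("trace shorter than a segment is rejected", {
  tr <- activity_trace(1e-3, matrix(0L, 100, 1), N = 10)
  expect_error(power_spectrum(tr, 1), "shorter")
})

test_that("renewal spectrum limits: Poisson value at high frequency and dead-time rate", {
  pop <- population_params(N = 500, u_rest = 30)
  sp <- renewal_spectrum(pop, 30, freqs = c(1:10, 2000, 3000))
  expect_equal(sp$power[11, 1], sp$rate / 500, tolerance = 0.02)
  expect_equal(sp$power[12, 1], sp$rate / 500, tolerance = 0.02)
  # constant hazard with dead time: r = 1/(t_ref + 1/lambda0)
  glm <- population_params(N = 100, u_rest = 18, t_ref = 0.004,
                           model_variant = "GLM")
  lam0 <- escape_rate(18, glm$u_th, glm$c, glm$delta_u)
  rn <- renewal_stats(glm, 18, quad_dt = 2e-6)
  expect_equal(rn$rate, 1 / (glm$t_ref + 1 / lam0), tolerance = 1e-8)
  # CV of the dead-time Poisson process: CV = 1 - r t_ref
  expect_equal(rn$cv, 1 - rn$rate * glm$t_ref, tolerance = 1e-6)
})

test_that("renewal quadrature is converged at the default resolution", {
  pop <- population_params(N = 500, u_rest = 30)
  f <- c(1, 10, 100, 400)
  s1 <- renewal_spectrum(pop, 30, f)          # default grid (~7 us)
  s2 <- renewal_spectrum(pop, 30, f, quad_dt = 3.5e-6) # 2x refinement
  expect_lt(max(abs(s1$power - s2$power) / s2$power), 1e-3)
  expect_equal(s1$rate, s2$rate, tolerance = 1e-5)
})

test_that("renewal spectrum errors when the rate vanishes", {
  pop <- population_params(N = 10, u_rest = -40)
  expect_error(renewal_spectrum(pop, -40, 1:10), "rate vanishes")
})

test_that("isi statistics: dead-time Poisson CV and input validation", {
  withr::with_seed(3, isi <- 0.004 + rexp(5000, 50))
  st <- isi_stats(isi)
  r <- 1 / (0.004 + 1 / 50)
  expect_equal(st$rate, r, tolerance = 0.05)
  expect_equal(st$cv, 1 - r * 0.004, tolerance = 0.05)
  expect_error(isi_stats(isi[1:50]), "ISIs")
})

test_that("bursty neurons show a bimodal ISI distribution", {
  pre <- preset_adapting("bursty", N = 200)
  st <- sim_settings(dt = 2e-4, duration = 20, seed = 9, init = "free",
                     warmup = 2, record_raster = TRUE)
  tr <- run_micro(pre$spec, st)
  stats <- isi_stats(tr, breaks = seq(0, max(tr$raster$time_s) + 0.1,
                                      by = 0.01))
  expect_gt(stats$cv, 1) # burstiness: CV above the Poisson value
  # peak at short ISIs (within-burst) plus a long tail (between bursts)
  expect_gt(mean(stats$isi < 0.05), 0.3)
  expect_gt(mean(stats$isi > 0.3), 0.1)
})

test_that("PSTH mean and standard deviation across trials", {
  trials <- lapply(1:8, function(s)
    fixture_generator("poisson", seed = s, N = 200, rate = 15,
                      dt = 1e-3, duration = 5))
  ps <- psth_and_std(trials)
  expect_equal(dim(ps$mean), c(5000L, 1L))
  expect_equal(mean(ps$mean), 15, tolerance = 0.02)
  # i.i.d. Poisson bins: sd of A over trials ~ sqrt(r/(N dt))
  expect_equal(mean(ps$sd), sqrt(15 / (200 * 1e-3)), tolerance = 0.1)
  # identical trials have zero sd
  same <- psth_and_std(list(trials[[1]], trials[[1]]))
  expect_true(all(same$sd == 0))
  expect_error(psth_and_std(list(trials[[1]],
    fixture_generator("poisson", seed = 1, duration = 2))), "length")
})

test_that("dominance times recover a programmed square wave exactly", {
  tr <- fixture_generator("square_wave", seed = 1, N = 200, period = 2,
                          levels = c(2, 40), dt = 1e-3, duration = 60)
  dm <- dominance_times(tr)
  expect_equal(dm$mean, 1, tolerance = 0.01)
  expect_lt(dm$cv, 0.01)
  expect_equal(dm$n, 2 * 29, tolerance = 2)
})

test_that("memoryless telegraph switching gives CV 1 and no serial correlation", {
  tr <- fixture_generator("telegraph", seed = 4, N = 200, switch_rate = 1,
                          levels = c(2, 40), dt = 1e-3, duration = 400,
                          noisy = TRUE)
  dm <- dominance_times(tr)
  expect_equal(dm$cv, 1, tolerance = 0.15)
  expect_lt(abs(dm$serial_correlation), 0.15)
  expect_gt(dm$n, 100)
})

test_that("dominance detection is invariant to population relabeling", {
  tr <- fixture_generator("telegraph", seed = 6, N = 200, switch_rate = 2,
                          dt = 1e-3, duration = 100, noisy = TRUE)
  sw <- tr
  sw$activity <- sw$activity[, 2:1]
  sw$counts <- sw$counts[, 2:1]
  d1 <- dominance_times(tr)
  d2 <- dominance_times(sw)
  expect_equal(sort(d1$durations), sort(d2$durations))
})

test_that("too few switches raise an informative error", {
  tr <- fixture_generator("square_wave", seed = 1, period = 20,
                          dt = 1e-3, duration = 30)
  expect_error(dominance_times(tr), "switches")
})
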