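#' Power spectrum of a stationary population activity
#'
#' Segment-averaged periodogram
#' \eqn{\tilde C(f) = \langle |\tilde A(f;T)|^2 \rangle / T} of the
#' binned population activity, with non-overlapping rectangular-window
#' segments and per-segment mean removal. The normalization is such that
#' a population of `N` independent Poisson neurons with rate `r` gives a
#' flat spectrum at `r/N`. Remove any transient before calling (e.g. by
#' dropping the initial part of the trace).
#'
#' @param trace an [activity_trace()].
#' @param segment_length segment length `T` in s; the frequency
#'   resolution is `1/T`.
#' @param pops columns (populations) to analyze; default all.
#' @return A list of class `spectrum_estimate`: `frequencies` (Hz, from
#'   `1/T` up to the Nyquist frequency), `power` (matrix, one column per
#'   population, units 1/s), `n_segments`, `segment_length`.
#' @export
power_spectrum <- function(trace, segment_length, pops = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  dt <- trace$dt
  nlen <- as.integer(round(segment_length / dt))
  n <- nrow(trace$activity)
  if (nlen < 2 || n < nlen) stop("trace is shorter than one segment")
  n_seg <- n %/% nlen
  if (is.null(pops)) pops <- seq_len(ncol(trace$activity))
  Tseg <- nlen * dt
  n_freq <- nlen %/% 2
  pow <- matrix(0, n_freq, length(pops))
  for (j in seq_along(pops)) {
    x <- trace$activity[seq_len(n_seg * nlen), pops[j]]
    segs <- matrix(x, nrow = nlen, ncol = n_seg)
    segs <- sweep(segs, 2, colMeans(segs))
    ft <- stats::mvfft(segs)
    per <- dt^2 * Mod(ft)^2 / Tseg
    pow[, j] <- rowMeans(per)[2:(n_freq + 1)]
  }
  structure(list(frequencies = (1:n_freq) / Tseg, power = pow,
                 n_segments = n_seg, segment_length = Tseg),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectrum_estimate> %d frequencies (%.3g-%.3g Hz), %d segment(s) of %g s\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$n_segments, x$segment_length))
  invisible(x)
}

# Hazard, survival, ISI density and moments of a renewal GIF neuron under
# constant drive mu: the membrane relaxes from the reset potential,
# u(t,0) = mu + (u_r - mu) exp(-(t - t_ref)/tau_m) for t > t_ref, and the
# threshold carries (at most) the last spike's kernel contribution.
compute_renewal <- function(pop, mu, quad_dt = NULL, s_floor = 1e-12) {
  stopifnot(inherits(pop, "population_params"))
  if (is.null(quad_dt)) quad_dt <- pop$tau_m / 100
  # align the grid with the dead time so that the hazard jump at t_ref
  # falls on a grid point (the dead-time bins then contribute exactly 0)
  quad_dt <- pop$t_ref / max(1, round(pop$t_ref / quad_dt))
  t_max <- pop$t_ref + 20 * pop$tau_m
  repeat {
    tt <- seq(0, t_max, by = quad_dt)
    if (pop$model_variant == "GIF") {
      u <- mu + (pop$u_r - mu) * exp(-pmax(tt - pop$t_ref, 0) / pop$tau_m)
    } else {
      # GLM: no reset; the after-potential of the last spike rides on mu
      u <- rep(mu, length(tt))
      if (!is_empty_kernel(pop$eta)) {
        for (l in seq_along(pop$eta$J)) {
          u <- u + (pop$eta$J[l] / pop$eta$tau[l]) * exp(-tt / pop$eta$tau[l])
        }
      }
    }
    th <- pop$u_th + ifelse(tt >= pop$t_ref,
                            theta_kernel_eval(pop$theta, pmax(tt, pop$t_ref)),
                            Inf)
    # right-continuous hazard: lambda jumps at t_ref
    lam <- ifelse(tt >= pop$t_ref,
                  escape_rate(u, th, pop$c, pop$delta_u), 0)
    inc <- (lam[-1] + lam[-length(lam)]) / 2 * quad_dt
    inc[tt[-length(tt)] < pop$t_ref - 1e-12] <- 0 # dead-time bins
    cum <- c(0, cumsum(inc))
    S <- exp(-cum)
    if (S[length(S)] < s_floor || t_max > pop$t_ref + 2000 * pop$tau_m) break
    t_max <- t_max * 2
  }
  if (S[length(S)] > 1e-6) {
    stop("hazard is numerically zero; the stationary rate vanishes")
  }
  keep <- S >= s_floor | seq_along(S) <= 2L
  tt <- tt[keep]; lam <- lam[keep]; S <- S[keep]
  P <- lam * S
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * quad_dt
  m1 <- trap(S)               # mean ISI = integral of survival
  m2 <- 2 * trap(tt * S)      # second moment
  v <- m2 - m1^2
  list(t = tt, lam = lam, S = S, isi_density = P,
       rate = 1 / m1, cv = sqrt(max(v, 0)) / m1, quad_dt = quad_dt)
}

#' Renewal statistics of a population under constant drive
#'
#' Stationary firing rate, coefficient of variation and interspike
#' interval density of a (quasi-)renewal GIF neuron computed by numerical
#' quadrature of the hazard rate. Exact for non-adapting neurons; with a
#' spike-triggered kernel only the last spike's contribution is included,
#' so the result describes the renewal regime.
#'
#' @param pop a [population_params()].
#' @param mu constant total drive \eqn{\mu = u_{rest} + RI} in mV.
#' @param quad_dt quadrature step in s (default `tau_m/100`).
#' @return A list of class `renewal_stats`: `rate` (1/s), `cv`,
#'   `isi_t` and `isi_density` (the ISI density grid, 1/s).
#' @export
renewal_stats <- function(pop, mu, quad_dt = NULL) {
  rn <- compute_renewal(pop, mu, quad_dt)
  structure(list(rate = rn$rate, cv = rn$cv, isi_t = rn$t,
                 isi_density = rn$isi_density),
            class = "renewal_stats")
}

#' @export
print.renewal_stats <- function(x, ...) {
  cat(sprintf("<renewal_stats> rate = %.4g 1/s, CV = %.4g\n", x$rate, x$cv))
  invisible(x)
}

#' Analytic power spectrum of a population of renewal neurons
#'
#' For `N` independent renewal spike trains the population-activity power
#' spectrum is known in closed form from the Fourier transform
#' \eqn{\tilde P_{ISI}(f)} of the interspike-interval density:
#' \deqn{\tilde C(f) = \frac{r}{N}\,
#'   \frac{1 - |\tilde P_{ISI}(f)|^2}{|1 - \tilde P_{ISI}(f)|^2}.}
#' The high-frequency limit is the Poisson value `r/N`.
#'
#' @param pop a [population_params()] (non-adapting; renewal regime).
#' @param mu constant drive in mV.
#' @param freqs frequencies in Hz at which to evaluate the spectrum.
#' @param quad_dt quadrature step in s for the ISI density.
#' @return A `spectrum_estimate` with extra fields `rate` and `cv`.
#' @export
renewal_spectrum <- function(pop, mu, freqs, quad_dt = NULL) {
  if (is.null(quad_dt)) {
    # resolve the fastest requested oscillation in the Fourier integral
    # and, for the low-frequency limit (where 1 - P_ISI(f) is small and
    # cancellation amplifies quadrature error), the mean interspike
    # interval; the rate is pre-estimated on a coarse grid
    r_coarse <- compute_renewal(pop, mu, pop$tau_m / 50)$rate
    quad_dt <- min(pop$tau_m / 100, 1 / (100 * max(freqs)),
                   1 / (4000 * r_coarse))
  }
  rn <- compute_renewal(pop, mu, quad_dt)
  # Fourier transform of the ISI density by trapezoidal quadrature; the
  # density is zero before the dead time and jumps at t_ref, so the
  # grid point at t_ref carries half weight
  wts <- rep(rn$quad_dt, length(rn$t))
  wts[c(1, length(wts))] <- rn$quad_dt / 2
  i_ref <- which(abs(rn$t - pop$t_ref) < rn$quad_dt / 2)
  wts[i_ref] <- rn$quad_dt / 2
  ph <- outer(freqs, rn$t, function(f, t) 2i * pi * f * t)
  Pf <- as.vector(exp(ph) %*% (rn$isi_density * wts))
  pow <- (rn$rate / pop$N) * (1 - Mod(Pf)^2) / Mod(1 - Pf)^2
  structure(list(frequencies = freqs, power = matrix(pow, ncol = 1),
                 n_segments = NA_integer_, segment_length = NA_real_,
                 rate = rn$rate, cv = rn$cv),
            class = "spectrum_estimate")
}

#' Interspike-interval statistics from a spike raster
#'
#' Empirical firing rate, coefficient of variation and ISI histogram,
#' pooled over the neurons of one population.
#'
#' @param x either an [activity_trace()] carrying a raster, a raster data
#'   frame with columns `time_s`, `population`, `neuron`, or a numeric
#'   vector of ISIs in s.
#' @param population population to analyze when `x` is a raster.
#' @param min_isis minimum number of ISIs required (default 100).
#' @param breaks passed to [hist()] for the ISI histogram.
#' @return A list of class `isi_stats`: `rate` (1/s), `cv`, `isi`
#'   (vector of ISIs in s), `hist` (histogram object).
#' @export
isi_stats <- function(x, population = 1L, min_isis = 100L, breaks = 50) {
  if (inherits(x, "activity_trace")) {
    if (is.null(x$raster)) stop("trace carries no raster")
    x <- x$raster
  }
  if (is.data.frame(x)) {
    x <- x[x$population == population, ]
    isi <- unlist(lapply(split(x$time_s, x$neuron),
                         function(tt) diff(sort(tt))), use.names = FALSE)
  } else {
    isi <- as.numeric(x)
  }
  if (length(isi) < min_isis) {
    stop(sprintf("only %d ISIs available (need >= %d)", length(isi), min_isis))
  }
  h <- graphics::hist(isi, breaks = breaks, plot = FALSE)
  structure(list(rate = 1 / mean(isi),
                 cv = stats::sd(isi) / mean(isi),
                 isi = isi, hist = h),
            class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  cat(sprintf("<isi_stats> %d ISIs, rate = %.4g 1/s, CV = %.4g\n",
              length(x$isi), x$rate, x$cv))
  invisible(x)
}

#' Trial-averaged activity (PSTH) and its standard deviation
#'
#' Per-bin mean and standard deviation of the population activity across
#' aligned, equal-length trials, at the resolution of the traces.
#'
#' @param traces list of [activity_trace()] objects with identical bin
#'   width, length and populations.
#' @return A list with `time`, `mean` and `sd` (bins x populations
#'   matrices, 1/s), and `n_trials`.
#' @export
psth_and_std <- function(traces) {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, TRUE, "activity_trace")))
  dims <- vapply(traces, function(tr) dim(tr$activity), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all trials must have the same length and number of populations")
  }
  arr <- simplify2array(lapply(traces, function(tr) tr$activity))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (length(traces) > 1) apply(arr, c(1, 2), stats::sd) else mu * 0
  list(time = traces[[1]]$time, mean = mu, sd = sdv, n_trials = length(traces))
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

detect_high_episodes <- function(x, t, th_lo, th_hi) {
  state <- NA
  starts <- numeric(0); ends <- numeric(0)
  open <- NA_real_
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    if (is.na(state)) {
      if (x[i] >= th_hi) state <- 1L else if (x[i] <= th_lo) state <- 0L
      next
    }
    if (state == 0L && x[i] >= th_hi) {
      state <- 1L
      open <- t[i]
    } else if (state == 1L && x[i] <= th_lo) {
      state <- 0L
      if (!is.na(open)) { # drop the first, left-censored episode
        starts <- c(starts, open)
        ends <- c(ends, t[i])
      }
      open <- NA_real_
    }
  }
  data.frame(start = starts, end = ends, duration = ends - starts)
}

#' Dominance-time statistics of a bistable activity trace
#'
#' Detects residence episodes in the high-activity state of competing
#' populations: the activity is low-pass filtered by a centered moving
#' average (default 100 ms), the low- and high-state activity levels are
#' estimated by a two-component split of the pooled smoothed values, and
#' episodes are detected with hysteresis thresholds at 40% and 60% of the
#' distance between the two levels (an episode starts when the smoothed
#' activity crosses the upper threshold from below and ends when it falls
#' below the lower one). Left/right-censored episodes are discarded.
#'
#' @param trace an [activity_trace()]; with two or more populations the
#'   columns in `pops` (default the first two) are analyzed separately
#'   and their episodes pooled, with a single-column trace only that
#'   signal is used.
#' @param smooth_window moving-average window in s (default 0.1).
#' @param thresholds optional length-2 numeric `c(lo, hi)` overriding the
#'   automatic hysteresis thresholds (in activity units, 1/s).
#' @param pops columns to analyze.
#' @return A list of class `dominance_times`: `durations` (s, pooled),
#'   `mean`, `cv`, `serial_correlation` (lag-1, within population,
#'   count-weighted), `n`, `thresholds`, `levels`, `episodes`.
#' @export
dominance_times <- function(trace, smooth_window = 0.1, thresholds = NULL,
                            pops = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  if (is.null(pops)) {
    pops <- seq_len(min(2L, ncol(trace$activity)))
  }
  w <- max(1L, as.integer(round(smooth_window / trace$dt)))
  sm <- lapply(pops, function(j) moving_average(trace$activity[, j], w))
  pooled <- unlist(sm)
  pooled <- pooled[!is.na(pooled)]
  if (is.null(thresholds)) {
    km <- stats::kmeans(pooled,
                        centers = matrix(stats::quantile(pooled, c(0.1, 0.9)),
                                         ncol = 1))
    lev <- sort(as.numeric(km$centers))
    thresholds <- lev[1] + c(0.4, 0.6) * diff(lev)
  } else {
    lev <- c(NA_real_, NA_real_)
  }
  eps <- lapply(seq_along(pops), function(j) {
    e <- detect_high_episodes(sm[[j]], trace$time, thresholds[1],
                              thresholds[2])
    if (nrow(e)) e$population <- pops[j]
    e
  })
  episodes <- do.call(rbind, eps)
  durations <- episodes$duration
  if (length(durations) < 10L) {
    stop(sprintf("only %d completed switches detected (need >= 10)",
                 length(durations)))
  }
  sc <- vapply(eps, function(e) {
    if (nrow(e) < 3 || stats::sd(e$duration) == 0) return(NA_real_)
    stats::cor(e$duration[-nrow(e)], e$duration[-1])
  }, 0)
  nn <- vapply(eps, nrow, 0L)
  ok <- !is.na(sc) & nn >= 3
  serial <- if (any(ok)) sum(sc[ok] * nn[ok]) / sum(nn[ok]) else NA_real_
  structure(list(durations = durations, mean = mean(durations),
                 cv = stats::sd(durations) / mean(durations),
                 serial_correlation = serial, n = length(durations),
                 thresholds = thresholds, levels = lev, episodes = episodes),
            class = "dominance_times")
}

#' @export
print.dominance_times <- function(x, ...) {
  cat(sprintf(
    "<dominance_times> %d episodes, mean = %.3g s, CV = %.3g, lag-1 corr = %.3g\n",
    x$n, x$mean, x$cv, x$serial_correlation))
  invisible(x)
}
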