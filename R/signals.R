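#' Synthetic validation signals
#'
#' Generators for traces with known autocorrelation structure, used to
#' validate the coherence estimators independently of the neural model.
#' All generators return an `"fhn_trajectory"`-compatible object holding a
#' single trace, so they flow through [compute_coherence()] unchanged.
#'
#' @name validation_signals
#' @keywords internal
NULL

signal_trajectory <- function(trace, dt, t_transient = 0) {
  structure(list(t = dt * (seq_along(trace) - 1L),
                 V = matrix(trace, nrow = 1),
                 w = NULL,
                 layer = factor("E", levels = c("E", "I")), N_E = 1L,
                 params = list(t_transient = t_transient, dt = dt)),
            class = "fhn_trajectory")
}

#' Ornstein-Uhlenbeck trace with known correlation time
#'
#' Exact-discretization recursion
#' `x[k+1] = x[k] exp(-dt/tau_c) + sigma sqrt(1 - exp(-2 dt/tau_c)) eta`,
#' started from the stationary law `N(mu, sigma^2)`. Its true normalized
#' autocorrelation is `exp(-tau/tau_c)`, so the characteristic correlation
#' time is `tau_c / 2` analytically. Exactness (rather than Euler stepping)
#' means any estimator error observed on these fixtures is attributable to
#' the estimator alone.
#'
#' @param tau_c Relaxation time (> 0).
#' @param sigma Stationary standard deviation.
#' @param mu Stationary mean.
#' @param duration Record length (time units).
#' @param dt Sampling step.
#' @param seed Integer seed.
#' @return An `"fhn_trajectory"` with one row.
#' @export
generate_ou <- function(tau_c, sigma = 1, mu = 0, duration = 500 * tau_c,
                        dt = tau_c / 20, seed = 1L) {
  stopifnot(tau_c > 0, sigma >= 0, duration > 0, dt > 0)
  set.seed(seed)
  n <- floor(duration / dt) + 1L
  rho <- exp(-dt / tau_c)
  innov_sd <- sigma * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  eta <- stats::rnorm(n - 1L)
  for (k in seq_len(n - 1L)) x[k + 1L] <- x[k] * rho + innov_sd * eta[k]
  signal_trajectory(mu + x, dt)
}

#' Sinusoidal trace
#'
#' `A sin(omega t)`; its normalized autocorrelation over an integer number
#' of periods is `cos(omega tau)`.
#'
#' @param omega Angular frequency (> 0).
#' @param A Amplitude.
#' @param duration Record length; for clean closed-form checks use an
#'   integer number of periods `2 pi / omega`.
#' @param dt Sampling step.
#' @return An `"fhn_trajectory"` with one row.
#' @export
generate_sine <- function(omega, A = 1, duration = 200 * pi / omega,
                          dt = (2 * pi / omega) / 64) {
  stopifnot(omega > 0, duration > 0, dt > 0)
  tt <- seq(0, duration, by = dt)
  signal_trajectory(A * sin(omega * tt), dt)
}

#' White-noise trace
#'
#' I.i.d. standard normal samples; the true autocorrelation is 1 at lag 0
#' and 0 elsewhere.
#'
#' @param n_samples Number of samples.
#' @param dt Sampling step.
#' @param seed Integer seed.
#' @return An `"fhn_trajectory"` with one row.
#' @export
generate_white <- function(n_samples, dt = 0.05, seed = 1L) {
  set.seed(seed)
  signal_trajectory(stats::rnorm(n_samples), dt)
}

#' Jittered pulse train
#'
#' A stereotyped raised-cosine bump placed at times
#' `t_k = k * period + jitter_k`, `jitter_k ~ N(0, jitter_sd^2)` i.i.d.
#' Emulates spiking with controllable regularity: zero jitter gives a
#' strictly periodic signal; growing jitter degrades periodicity and must
#' lower the characteristic correlation time. The bump shape is arbitrary
#' (any brief stereotyped waveform yields the same ordering).
#'
#' @param period Inter-pulse period (> 0).
#' @param jitter_sd Standard deviation of the Gaussian timing jitter;
#'   required below `period / 3` so pulses stay ordered.
#' @param width Bump half-duration (default `period / 10`).
#' @param duration Record length.
#' @param dt Sampling step.
#' @param seed Integer seed.
#' @return An `"fhn_trajectory"` with one row.
#' @export
generate_pulse_train <- function(period, jitter_sd = 0, width = period / 10,
                                 duration = 200 * period, dt = period / 50,
                                 seed = 1L) {
  stopifnot(period > 0, jitter_sd >= 0, duration > 0, dt > 0)
  if (jitter_sd >= period / 3) {
    stop("jitter_sd must stay below period / 3 to keep pulses ordered")
  }
  set.seed(seed)
  n <- floor(duration / dt) + 1L
  tt <- dt * (0:(n - 1L))
  k <- 0:floor(duration / period)
  centers <- k * period + if (jitter_sd > 0) stats::rnorm(length(k), 0, jitter_sd) else 0
  x <- numeric(n)
  for (tc in centers) {
    i0 <- max(1L, ceiling((tc - width) / dt) + 1L)
    i1 <- min(n, floor((tc + width) / dt) + 1L)
    if (i1 >= i0) {
      u <- (tt[i0:i1] - tc) / width
      x[i0:i1] <- x[i0:i1] + 0.5 * (1 + cos(pi * u))
    }
  }
  out <- signal_trajectory(x, dt)
  attr(out, "n_pulses") <- length(centers)
  out
}
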