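#' Configuration for coherence estimation
#'
#' @param tau_max Maximum lag (time units) for the autocorrelation function
#'   and the upper limit of the correlation-time integral. Must not exceed
#'   half the analysed record so that all lags are well estimated.
#' @param var_eps Variance floor: traces with variance at or below it are
#'   flagged as silent and assigned a correlation time of 0 (no oscillation,
#'   no coherence), keeping the zero-noise limit well-defined.
#' @return An object of class `"fhn_coh_config"`.
#' @export
coherence_config <- function(tau_max = 200, var_eps = 1e-12) {
  stopifnot(tau_max > 0, var_eps >= 0)
  structure(list(tau_max = tau_max, var_eps = var_eps),
            class = "fhn_coh_config")
}

#' Normalized autocorrelation of a single trace
#'
#' `C(tau) = <Vt(t) Vt(t + tau)> / (<V^2> - <V>^2)` with
#' `Vt = V - <V>`, time averages over the supplied record. The biased
#' estimator (normalizing by the full record length at every lag) is used:
#' it guarantees `|C| <= 1` and a positive-semidefinite correlation
#' structure. Computed via FFT with zero padding.
#'
#' @param trace Numeric vector, sampled uniformly at spacing `dt`.
#' @param dt Sampling interval (time units).
#' @param config An [coherence_config()] object; lags `0..tau_max` on the
#'   sampling grid are returned.
#' @return List with `lag` (time units) and `C`; `NULL` if the trace
#'   variance is at or below `config$var_eps` (silent trace).
#' @export
autocorrelation <- function(trace, dt, config = coherence_config()) {
  n <- length(trace)
  n_lag <- min(floor(config$tau_max / dt), n - 1L)
  v <- trace - mean(trace)
  va <- mean(v^2)
  if (va <= config$var_eps) return(NULL)
  n2 <- stats::nextn(n + n_lag + 1L, 2)
  ft <- stats::fft(c(v, rep(0, n2 - n)))
  ac <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / n2
  list(lag = dt * (0:n_lag), C = ac[1:(n_lag + 1L)] / (n * va))
}

#' Characteristic correlation time
#'
#' `T = integral of C(tau)^2 over [0, tau_max]` by trapezoidal quadrature on
#' the lag grid. Large `T` indicates a strongly periodic autocorrelation,
#' i.e. coherent activity.
#'
#' @param C Numeric vector of autocorrelation values on a uniform lag grid.
#' @param dlag Lag spacing (time units).
#' @return Non-negative scalar.
#' @export
correlation_time <- function(C, dlag) {
  if (length(C) < 2) return(0)
  C2 <- C^2
  dlag * (sum(C2) - (C2[1] + C2[length(C2)]) / 2)
}

#' Population and layer averages of correlation times
#'
#' Arithmetic means of the per-neuron correlation times over all neurons,
#' the excitatory layer, and the inhibitory layer. An empty layer yields
#' `NA` for its average (undefined, not zero). The identity
#' `N_E * T_bar_E + N_I * T_bar_I = N * T_bar` holds exactly.
#'
#' @param T_i Numeric vector of per-neuron correlation times.
#' @param layer Layer labels (`"E"`/`"I"`), same length as `T_i`.
#' @return Named list `T_bar`, `T_bar_E`, `T_bar_I`.
#' @export
layer_averages <- function(T_i, layer) {
  stopifnot(length(T_i) == length(layer))
  is_E <- layer == "E"
  list(T_bar = mean(T_i),
       T_bar_E = if (any(is_E)) mean(T_i[is_E]) else NA_real_,
       T_bar_I = if (any(!is_E)) mean(T_i[!is_E]) else NA_real_)
}

#' Coherence of a simulated trajectory
#'
#' Per-neuron normalized autocorrelation and characteristic correlation
#' times over the post-transient window, with population and layer
#' averages. Silent neurons (variance at or below the configured floor) get
#' `T_i = 0` and are flagged.
#'
#' @param trajectory An `"fhn_trajectory"` object (or any list with `t`,
#'   `V`, `layer` and `params$t_transient`).
#' @param config An [coherence_config()] object. `tau_max` must be at most
#'   half the post-transient record.
#' @param keep_C If `TRUE`, the per-neuron autocorrelation matrix is
#'   retained in the result.
#' @return An object of class `"fhn_coherence"`: list with `T_i`, `T_bar`,
#'   `T_bar_E`, `T_bar_I`, `silent` (logical vector), `lag` and optionally
#'   `C` (neurons x lags).
#' @export
compute_coherence <- function(trajectory, config = coherence_config(),
                              keep_C = FALSE) {
  tt <- trajectory$t
  dt <- tt[2] - tt[1]
  keep <- tt > trajectory$params$t_transient
  window <- max(tt) - trajectory$params$t_transient
  if (config$tau_max > window / 2) {
    stop("tau_max (", config$tau_max, ") exceeds half the post-transient record (",
         window / 2, ")")
  }
  Vp <- trajectory$V[, keep, drop = FALSE]
  N <- nrow(Vp)
  n <- ncol(Vp)
  n_lag <- min(floor(config$tau_max / dt), n - 1L)
  lag <- dt * (0:n_lag)
  T_i <- numeric(N)
  silent <- logical(N)
  Cmat <- if (keep_C) matrix(NA_real_, N, n_lag + 1L) else NULL
  for (i in seq_len(N)) {
    ac <- autocorrelation(Vp[i, ], dt, config)
    if (is.null(ac)) { silent[i] <- TRUE; next }
    if (keep_C) Cmat[i, ] <- ac$C
    T_i[i] <- correlation_time(ac$C, dt)
  }
  avg <- layer_averages(T_i, trajectory$layer)
  structure(c(list(T_i = T_i, silent = silent, lag = lag, C = Cmat), avg),
            class = "fhn_coherence")
}

#' @export
print.fhn_coherence <- function(x, ...) {
  cat(sprintf("Coherence over %d neurons (%d silent)\n",
              length(x$T_i), sum(x$silent)))
  cat(sprintf("  T_bar = %.4g, T_bar_E = %.4g, T_bar_I = %.4g\n",
              x$T_bar, x$T_bar_E, x$T_bar_I))
  invisible(x)
}
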