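# shared fixture builders: small, fast parameter sets for unit tests

std_net_params <- function(...) {
  do.call(network_params,
          utils::modifyList(list(N = 200, gamma_I = 0.2, R_th = 0.126,
                                 beta = 2.5, delta = 0.5, xi = 0.5,
                                 kbar_I = 2.0, seed = 101L),
                            list(...)))
}

# short desk-scale dynamics for tests that only need a plausible trajectory
fast_dyn_params <- function(...) {
  do.call(dynamics_params,
          utils::modifyList(list(D = 10, t_total = 250, t_transient = 50),
                            list(...)))
}

fast_coh_config <- function(...) coherence_config(tau_max = 80, ...)

# hand-built geometry at fixed positions (no RNG)
manual_geometry <- function(x, y, layer) {
  layer <- factor(layer, levels = c("E", "I"))
  structure(list(x = x, y = y, layer = layer,
                 N_E = sum(layer == "E"), N_I = sum(layer == "I")),
            class = "fhn_geometry")
}

# direct-summation biased autocorrelation: the independent oracle against
# which the FFT implementation is checked
acf_direct <- function(v, n_lag) {
  v <- v - mean(v)
  n <- length(v)
  va <- mean(v^2)
  vapply(0:n_lag, function(k) {
    sum(v[1:(n - k)] * v[(1 + k):n]) / (n * va)
  }, numeric(1))
}
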