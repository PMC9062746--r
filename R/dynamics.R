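#' Dynamics parameters for the coupled stochastic FitzHugh-Nagumo system
#'
#' Neuron constants `a`, `b`, `c` place every neuron in the excitable regime
#' (stable rest state, large excursion on supra-threshold perturbation).
#' The four coupling coefficients are indexed presynaptic-type first:
#' `K_EE` and `K_II` scale intralayer input, `K_EI` scales excitatory input
#' to inhibitory neurons, `K_IE` inhibitory input to excitatory neurons.
#' Excitatory input enters with a plus sign, inhibitory input with a minus
#' sign.
#'
#' The noise term is discretized as `V <- V + dt * (drift + D * eta)` with
#' `eta ~ N(0,1)` redrawn independently per neuron and step: `eta` is treated
#' as a unit-variance Gaussian force held constant over one step, so the
#' effective white-noise intensity is `D * sqrt(dt)` at the reference step
#' `dt = 0.01`. `D` values quoted throughout the package refer to this
#' convention.
#'
#' @param a,b,c FitzHugh-Nagumo constants (defaults 0.8, 0.9, 4.5).
#' @param D Noise intensity (>= 0), applied to the fast variable only.
#' @param K_EE,K_EI,K_IE,K_II Coupling strengths (>= 0; default 0.2 each).
#' @param dt Integration step (time units; default 0.01).
#' @param t_total Simulated duration.
#' @param t_transient Initial span discarded from analysis
#'   (`t_transient < t_total`).
#' @param stride Recording stride in steps (states kept every
#'   `stride * dt` time units; default 5).
#' @param seed Integer seed for the integrator's noise stream.
#' @return An object of class `"fhn_dyn_params"`.
#' @export
dynamics_params <- function(a = 0.8, b = 0.9, c = 4.5, D = 10,
                            K_EE = 0.2, K_EI = 0.2, K_IE = 0.2, K_II = 0.2,
                            dt = 0.01, t_total = 600, t_transient = 100,
                            stride = 5L, seed = 1L) {
  stopifnot(dt > 0, t_total > 0, t_transient >= 0, t_transient < t_total,
            D >= 0, K_EE >= 0, K_EI >= 0, K_IE >= 0, K_II >= 0,
            stride >= 1, b != 0)
  structure(list(a = a, b = b, c = c, D = D,
                 K_EE = K_EE, K_EI = K_EI, K_IE = K_IE, K_II = K_II,
                 dt = dt, t_total = t_total, t_transient = t_transient,
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "fhn_dyn_params")
}

#' Resting state of the noise-free uncoupled neuron
#'
#' Solves the nullcline intersection `V - V^3/3 - (V + a)/b = 0` by bracketed
#' root-finding and returns the stable equilibrium `(V*, w*)` with
#' `w* = (V* + a)/b`. Stability is verified from the eigenvalues of the
#' Jacobian of the noise-free uncoupled system; if several real roots exist
#' the stable one is returned, and an error is raised if none is stable.
#'
#' @param params An [dynamics_params()] object (only `a`, `b`, `c` used).
#' @return Named numeric vector `c(V = V_star, w = w_star)`.
#' @examples
#' fhn_fixed_point(dynamics_params())  # approx c(V = -1.307, w = -0.563)
#' @export
fhn_fixed_point <- function(params = dynamics_params()) {
  a <- params$a; b <- params$b; c <- params$c
  g <- function(V) V - V^3 / 3 - (V + a) / b
  # all real roots of the cubic -V^3/3 + (1 - 1/b) V - a/b
  rts <- polyroot(c(-a / b, 1 - 1 / b, 0, -1 / 3))
  real <- Re(rts[abs(Im(rts)) < 1e-8])
  real <- vapply(real, function(r)
    stats::uniroot(g, c(r - 0.1, r + 0.1), tol = 1e-14,
                   extendInt = "yes")$root, numeric(1))
  stable <- vapply(real, function(V) {
    J <- matrix(c(c * (1 - V^2), -c, 1 / c, -b / c), 2, 2, byrow = TRUE)
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }, logical(1))
  if (!any(stable)) stop("no stable equilibrium for these parameters")
  V_star <- real[stable][1]
  if (abs(g(V_star)) > 1e-10) stop("root residual above tolerance")
  c(V = V_star, w = (V_star + a) / b)
}

#' Diffusive coupling input sums
#'
#' For every neuron `i`, sums of presynaptic stimuli split by presynaptic
#' type: `V_i^E = sum_{j <= N_E} M[j, i] (V_j - V_i)` and
#' `V_i^I = sum_{j > N_E} M[j, i] (V_j - V_i)`. Intralayer and interlayer
#' neighbours both contribute, discriminated only by the presynaptic layer.
#'
#' @param V Numeric state vector of length `N`.
#' @param network An `"fhn_network"` object.
#' @return List with numeric vectors `V_E` and `V_I` of length `N`.
#' @export
coupling_inputs <- function(V, network) {
  p <- network$params
  stopifnot(length(V) == p$N)
  eidx <- seq_len(p$N_E)
  ME <- network$M[eidx, , drop = FALSE]     # presynaptic excitatory rows
  MI <- network$M[-eidx, , drop = FALSE]
  V_E <- as.vector(crossprod(ME, V[eidx])) - colSums(ME) * V
  V_I <- as.vector(crossprod(MI, V[-eidx])) - colSums(MI) * V
  list(V_E = V_E, V_I = V_I)
}

#' Deterministic drift of the coupled system
#'
#' Evaluates the noise-free time-derivatives: for excitatory neurons
#' `dV = c (V - V^3/3 - w) + K_EE V^E - K_IE V^I`, for inhibitory neurons
#' `dV = c (V - V^3/3 - w) + K_EI V^E - K_II V^I`, and for all neurons
#' `dw = (V - b w + a) / c`.
#'
#' @param V,w State vectors of length `N`.
#' @param inputs Coupling sums as returned by [coupling_inputs()].
#' @param params An [dynamics_params()] object.
#' @param layer Factor/character vector of layer labels (`"E"`/`"I"`).
#' @return List with vectors `dV` and `dw`.
#' @export
fhn_drift <- function(V, w, inputs, params, layer) {
  stopifnot(length(V) == length(w), length(V) == length(layer))
  is_E <- layer == "E"
  kE <- ifelse(is_E, params$K_EE, params$K_EI)
  kI <- ifelse(is_E, params$K_IE, params$K_II)
  list(dV = params$c * (V - V^3 / 3 - w) + kE * inputs$V_E - kI * inputs$V_I,
       dw = (V - params$b * w + params$a) / params$c)
}

#' Integrate the stochastic dynamics on a network
#'
#' Steps the coupled system with a stochastic Heun scheme: the drift is
#' advanced by the two-stage trapezoidal rule (second-order accurate in the
#' noise-free limit) and the noise adds `D * eta * dt` to `V` each step
#' (noise on the fast variable only, independent across neurons and steps).
#' Every neuron starts at the stable rest state `(V*, w*)`. The noise path comes from a
#' dedicated counter-seeded generator, so identical `(network, params)` give
#' bitwise-identical trajectories. Integration aborts with the offending
#' step index if the state leaves the finite range (diagnostic for too large
#' a step).
#'
#' @param network An `"fhn_network"` object.
#' @param params An [dynamics_params()] object.
#' @param init Optional list with numeric vectors `V`, `w` overriding the
#'   rest-state initial condition (recycled to length `N`).
#' @return An object of class `"fhn_trajectory"`: list with time grid `t`
#'   (spacing `dt * stride`, starting at 0), `N x T` matrices `V` and `w`,
#'   `layer`, `N_E`, and the generating `params`.
#' @export
integrate_network <- function(network, params, init = NULL) {
  stopifnot(inherits(network, "fhn_network"), inherits(params, "fhn_dyn_params"))
  p <- network$params
  fp <- fhn_fixed_point(params)
  V0 <- rep_len(if (is.null(init)) fp[["V"]] else init$V, p$N)
  w0 <- rep_len(if (is.null(init)) fp[["w"]] else init$w, p$N)
  edges <- rbind(network$intra_edges, network$intra_edges[, c(2, 1), drop = FALSE],
                 network$inter_edges)
  n_steps <- round(params$t_total / params$dt)
  res <- .em_integrate(p$N, p$N_E,
                       as.integer(edges[, 1]) - 1L, as.integer(edges[, 2]) - 1L,
                       V0, w0,
                       params$a, params$b, params$c, params$D,
                       params$K_EE, params$K_EI, params$K_IE, params$K_II,
                       params$dt, as.integer(n_steps), params$stride,
                       as.double(params$seed %% 2^31), TRUE)
  structure(list(t = seq(0, by = params$dt * params$stride,
                         length.out = res$n_recorded),
                 V = res$V, w = res$w,
                 layer = network$geometry$layer, N_E = p$N_E,
                 params = params),
            class = "fhn_trajectory")
}

#' Detect spikes by threshold crossing
#'
#' A spike is recorded at each upward crossing of `threshold` by the
#' membrane potential, with the crossing time refined by linear
#' interpolation between samples. A refractory guard suppresses any second
#' crossing within `refractory` time units. Only crossings after
#' `t_transient` are kept.
#'
#' @param trajectory An `"fhn_trajectory"` object.
#' @param threshold Potential threshold; must exceed the resting potential
#'   `V*`.
#' @param refractory Minimum inter-spike interval (time units).
#' @return An object of class `"fhn_raster"`: list of per-neuron numeric
#'   vectors of strictly increasing spike times, with attribute `t_range`.
#' @export
detect_spikes <- function(trajectory, threshold = 1.0, refractory = 1.0) {
  stopifnot(inherits(trajectory, "fhn_trajectory"))
  fp <- fhn_fixed_point(trajectory$params)
  if (threshold <= fp[["V"]]) {
    stop("spike threshold (", threshold, ") must exceed the resting potential V* = ",
         round(fp[["V"]], 4))
  }
  tt <- trajectory$t
  t_tr <- trajectory$params$t_transient
  spikes <- apply(trajectory$V, 1, function(v) {
    up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
    if (length(up) == 0) return(numeric(0))
    frac <- (threshold - v[up]) / (v[up + 1] - v[up])
    st <- tt[up] + frac * (tt[up + 1] - tt[up])
    st <- st[st > t_tr]
    if (length(st) > 1) {
      keep <- c(TRUE, rep(FALSE, length(st) - 1))
      last <- st[1]
      for (k in seq_along(st)[-1]) {
        if (st[k] - last >= refractory) { keep[k] <- TRUE; last <- st[k] }
      }
      st <- st[keep]
    }
    st
  }, simplify = FALSE)
  structure(spikes, class = "fhn_raster",
            t_range = c(t_tr, trajectory$params$t_total))
}

#' Mean firing rates per neuron
#'
#' Spike counts from [detect_spikes()] divided by the analysed (post-
#' transient) duration.
#'
#' @param raster An `"fhn_raster"` object.
#' @return Numeric vector of rates (spikes per time unit).
#' @export
firing_rates <- function(raster) {
  tr <- attr(raster, "t_range")
  vapply(raster, length, numeric(1)) / diff(tr)
}
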