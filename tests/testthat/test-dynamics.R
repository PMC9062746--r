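test_that("the rest state is a stable zero of the noise-free flow", {
  dp <- dynamics_params()
  fp <- fhn_fixed_point(dp)
  expect_equal(unname(fp["V"]), -1.3068, tolerance = 1e-3)
  expect_equal(unname(fp["w"]), -0.5631, tolerance = 1e-3)
  # residual of the nullcline equation
  g <- fp["V"] - fp["V"]^3 / 3 - (fp["V"] + dp$a) / dp$b
  expect_lt(abs(g), 1e-10)
  expect_equal(unname(fp["w"]), unname((fp["V"] + dp$a) / dp$b), tolerance = 1e-12)
  # Jacobian eigenvalues have negative real part
  J <- matrix(c(dp$c * (1 - fp["V"]^2), -dp$c, 1 / dp$c, -dp$b / dp$c),
              2, 2, byrow = TRUE)
  expect_true(all(Re(eigen(J)$values) < 0))
})

test_that("coupling sums are diffusive and split by presynaptic type", {
  p <- std_net_params()
  net <- build_network(p)
  # equal potentials: all coupling terms vanish
  inp <- coupling_inputs(rep(0.37, p$N), net)
  expect_equal(inp$V_E, rep(0, p$N))
  expect_equal(inp$V_I, rep(0, p$N))
  # single link j -> i with V_j - V_i = 1, j excitatory
  net0 <- net
  net0$M[] <- 0L
  net0$M[3, 170] <- 1L  # E neuron 3 onto I neuron 170
  V <- rep(0, p$N); V[3] <- 1
  inp <- coupling_inputs(V, net0)
  expect_equal(inp$V_E[170], 1)
  expect_equal(inp$V_I[170], 0)
  expect_equal(sum(abs(inp$V_E[-c(3, 170)])), 0)  # no other postsynaptic input
  # a neuron with no presynaptic links gets zero input
  expect_equal(inp$V_E[1], 0)
  expect_equal(inp$V_I[1], 0)
})

test_that("drift matches the model equations at reference points", {
  dp <- dynamics_params()
  p <- std_net_params()
  net <- build_network(p)
  zero_in <- list(V_E = rep(0, p$N), V_I = rep(0, p$N))
  d0 <- fhn_drift(rep(0, p$N), rep(0, p$N), zero_in, dp, net$geometry$layer)
  expect_equal(d0$dV, rep(0, p$N))
  expect_equal(d0$dw, rep(0.8 / 4.5, p$N))
  fp <- fhn_fixed_point(dp)
  dfp <- fhn_drift(rep(fp["V"], p$N), rep(fp["w"], p$N), zero_in, dp,
                   net$geometry$layer)
  expect_lt(max(abs(dfp$dV)), 1e-9)
  expect_lt(max(abs(dfp$dw)), 1e-9)
  # with equal K the postsynaptic type does not matter; with distinct K it does
  inp1 <- list(V_E = rep(1, p$N), V_I = rep(0, p$N))
  deq <- fhn_drift(rep(0, p$N), rep(0, p$N), inp1, dp, net$geometry$layer)
  expect_equal(var(deq$dV), 0)
  dp2 <- dynamics_params(K_EE = 0.3, K_EI = 0.1)
  dne <- fhn_drift(rep(0, p$N), rep(0, p$N), inp1, dp2, net$geometry$layer)
  expect_equal(unique(dne$dV[net$geometry$layer == "E"]), 0.3)
  expect_equal(unique(dne$dV[net$geometry$layer == "I"]), 0.1)
})

test_that("noise-free integration from rest stays at rest; seeds reproduce", {
  p <- std_net_params()
  net <- build_network(p)
  dp <- dynamics_params(D = 0, t_total = 100, t_transient = 10)
  traj <- integrate_network(net, dp)
  fp <- fhn_fixed_point(dp)
  expect_lt(max(abs(traj$V - fp["V"])), 1e-6)
  expect_lt(max(abs(traj$w - fp["w"])), 1e-6)
  # bitwise determinism with noise on
  dpn <- fast_dyn_params(seed = 33)
  t1 <- integrate_network(net, dpn)
  t2 <- integrate_network(net, dpn)
  expect_identical(t1$V, t2$V)
  t3 <- integrate_network(net, fast_dyn_params(seed = 34))
  expect_false(identical(t1$V, t3$V))
})

test_that("per-step noise increments have the advertised variance", {
  # single uncoupled neuron: V increments minus the two-stage drift update
  # are D * eta * dt, so their variance is (D * dt)^2
  p <- network_params(N = 2, gamma_I = 0.5, kbar_I = 0, R_th = 1e-9, seed = 1)
  net <- build_network(p)
  dp <- dynamics_params(D = 4, dt = 0.01, t_total = 100, t_transient = 1,
                        stride = 1L, seed = 12)
  traj <- integrate_network(net, dp)
  V <- traj$V[1, ]; w <- traj$w[1, ]
  n <- length(V) - 1
  fV <- function(V, w) dp$c * (V - V^3 / 3 - w)
  fw <- function(V, w) (V - dp$b * w + dp$a) / dp$c
  k1V <- fV(V[1:n], w[1:n]); k1w <- fw(V[1:n], w[1:n])
  k2V <- fV(V[1:n] + dp$dt * k1V, w[1:n] + dp$dt * k1w)
  resid <- V[2:(n + 1)] - V[1:n] - dp$dt / 2 * (k1V + k2V)
  expect_equal(var(resid), (dp$D * dp$dt)^2, tolerance = 0.05)
  expect_equal(mean(resid), 0, tolerance = 3 * dp$D * dp$dt / sqrt(n))
})

test_that("deterministic suprathreshold release gives one spike matching an ODE oracle", {
  p <- network_params(N = 2, gamma_I = 0.5, kbar_I = 0, R_th = 1e-9, seed = 1)
  net <- build_network(p)
  dp <- dynamics_params(D = 0, dt = 0.01, t_total = 100, t_transient = 0,
                        stride = 1L)
  fp <- fhn_fixed_point(dp)
  traj <- integrate_network(net, dp,
                            init = list(V = fp["V"] + 2, w = fp["w"]))
  # high-accuracy adaptive oracle on the same single-neuron system
  rhs <- function(t, y, parms) {
    list(c(parms$c * (y[1] - y[1]^3 / 3 - y[2]),
           (y[1] - parms$b * y[2] + parms$a) / parms$c))
  }
  sol <- deSolve::ode(y = c(fp["V"] + 2, fp["w"]), times = traj$t, func = rhs,
                      parms = dp, method = "ode45", atol = 1e-10, rtol = 1e-10)
  expect_lt(max(abs(traj$V[1, ] - sol[, 2])), 1e-3)
  # exactly one excursion, then return to within 1e-3 of rest
  raster <- detect_spikes(traj, threshold = 1.0)
  expect_identical(lengths(raster), c(1L, 1L))
  expect_lt(abs(traj$V[1, ncol(traj$V)] - fp["V"]), 1e-3)
})

test_that("step halving shrinks the noise-free discretization error at second order", {
  p <- network_params(N = 2, gamma_I = 0.5, kbar_I = 0, R_th = 1e-9, seed = 1)
  net <- build_network(p)
  fp <- fhn_fixed_point(dynamics_params())
  run_at <- function(dt) {
    dp <- dynamics_params(D = 0, dt = dt, t_total = 100, t_transient = 0,
                          stride = as.integer(round(0.05 / dt)))
    integrate_network(net, dp, init = list(V = fp["V"] + 2, w = fp["w"]))$V[1, ]
  }
  v1 <- run_at(0.01); v2 <- run_at(0.005); v3 <- run_at(0.0025)
  e12 <- max(abs(v1 - v2)); e23 <- max(abs(v2 - v3))
  # two-stage trapezoidal drift: successive-difference ratio about 4
  expect_gt(e12 / e23, 2.8)
  expect_lt(e12 / e23, 5.5)
})

test_that("a symmetric noise-free pair stays exactly symmetric", {
  p <- network_params(N = 4, gamma_I = 0.5, kbar_I = 0, R_th = 2, seed = 2)
  net <- build_network(p)  # E pair and I pair, fully linked within layers
  dp <- dynamics_params(D = 0, t_total = 50, t_transient = 0, stride = 1L)
  fp <- fhn_fixed_point(dp)
  traj <- integrate_network(net, dp, init = list(V = fp["V"] + 1.5, w = fp["w"]))
  expect_identical(traj$V[1, ], traj$V[2, ])
  expect_identical(traj$V[3, ], traj$V[4, ])
})

test_that("the rest state attracts nearby noise-free starts (basin test)", {
  p <- network_params(N = 2, gamma_I = 0.5, kbar_I = 0, R_th = 1e-9, seed = 1)
  net <- build_network(p)
  dp <- dynamics_params(D = 0, t_total = 150, t_transient = 0, stride = 10L)
  fp <- fhn_fixed_point(dp)
  set.seed(50)
  for (k in 1:25) {
    init <- list(V = fp["V"] + runif(2, -0.5, 0.5),
                 w = fp["w"] + runif(2, -0.5, 0.5))
    traj <- integrate_network(net, dp, init = init)
    expect_lt(max(abs(traj$V[, ncol(traj$V)] - fp["V"])), 1e-4)
  }
})

test_that("spike detection counts upward crossings with a refractory guard", {
  dp <- dynamics_params(t_total = 40, t_transient = 0)
  fp <- fhn_fixed_point(dp)
  mk_traj <- function(v) {
    structure(list(t = seq(0, 40, by = 0.05),
                   V = matrix(v, nrow = 1), w = NULL,
                   layer = factor("E", levels = c("E", "I")), N_E = 1L,
                   params = dp),
              class = "fhn_trajectory")
  }
  tt <- seq(0, 40, by = 0.05)
  flat <- mk_traj(rep(fp["V"], length(tt)))
  expect_identical(lengths(detect_spikes(flat)), 0L)
  # sine crossing the threshold k times upward
  sine <- mk_traj(2 * sin(2 * pi * tt / 8))  # 5 periods in 40 time units
  expect_identical(lengths(detect_spikes(sine, threshold = 1.0)), 5L)
  expect_error(detect_spikes(sine, threshold = -2), "threshold")
  # refractory guard collapses a burst of rapid crossings
  burst <- mk_traj(2 * sin(2 * pi * tt / 0.4))
  expect_lt(length(detect_spikes(burst, threshold = 1.0)[[1]]),
            sum(diff(2 * sin(2 * pi * tt / 0.4) >= 1) == 1))
})

test_that("inhibitory firing rates rise with the inhibitory fraction", {
  # probed below the resonance optimum (D = 5), where rates have not yet
  # saturated and the composition effect is visible
  rates <- function(gamma_I, seed) {
    p <- network_params(N = 200, gamma_I = gamma_I, seed = seed)
    net <- build_network(p)
    traj <- integrate_network(net, fast_dyn_params(D = 5, seed = seed + 1))
    r <- firing_rates(detect_spikes(traj))
    c(I = mean(r[net$geometry$layer == "I"]),
      E = mean(r[net$geometry$layer == "E"]))
  }
  lo <- rowMeans(vapply(1:5, function(s) rates(0.2, 900 + 7 * s), numeric(2)))
  hi <- rowMeans(vapply(1:5, function(s) rates(0.7, 950 + 7 * s), numeric(2)))
  expect_gt(hi[["I"]], lo[["I"]])   # more inhibitory neurons: higher I activity
  expect_gt(lo[["I"]], lo[["E"]])   # I activity is intrinsically higher
})
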