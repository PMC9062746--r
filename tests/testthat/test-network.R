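test_that("placement splits layers by index and stays in the unit square", {
  p <- network_params(N = 200, gamma_I = 0.2, seed = 1)
  expect_identical(p$N_E, 160L)
  expect_identical(p$N_I, 40L)
  set.seed(1)
  g <- place_neurons(p)
  expect_true(all(g$x >= 0 & g$x <= 1))
  expect_true(all(g$y >= 0 & g$y <= 1))
  expect_identical(as.character(g$layer), rep(c("E", "I"), c(160, 40)))
  # rounding of a non-integer N * gamma_I
  expect_identical(network_params(N = 15, gamma_I = 0.3)$N_I, 4L)
})

test_that("a single-layer network is allowed but flagged", {
  set.seed(1)
  expect_warning(place_neurons(network_params(N = 10, gamma_I = 0, kbar_I = 0)),
                 "single-layer")
  expect_warning(place_neurons(network_params(N = 10, gamma_I = 1, kbar_I = 0)),
                 "single-layer")
  # a nonzero interlayer target is unachievable without both layers
  expect_error(network_params(N = 10, gamma_I = 0), "unachievable")
})

test_that("intralayer edges follow the strict distance rule, within layer only", {
  g <- manual_geometry(x = c(0, 0.1, 0.2, 0.05), y = rep(0, 4),
                       layer = c("E", "E", "E", "I"))
  e <- build_intralayer(g, R_th = 0.126)
  pairs <- apply(e, 1, paste, collapse = "-")
  expect_true("1-2" %in% pairs)   # 0.1  < 0.126
  expect_true("2-3" %in% pairs)   # 0.1  < 0.126
  expect_false("1-3" %in% pairs)  # 0.2  > 0.126
  # neuron 4 is inhibitory: no cross-layer edge despite distance 0.05
  expect_false(any(e[, 1] == 4 | e[, 2] == 4))
  # boundary case is strict: distance exactly R_th is not an edge
  # (0.5 is exact in binary, so d == R_th holds without rounding slack)
  g2 <- manual_geometry(c(0, 0.5), c(0, 0), c("E", "E"))
  expect_identical(nrow(build_intralayer(g2, 0.5)), 0L)
})

test_that("intralayer edge sets are nested in R_th (degree monotone)", {
  p <- std_net_params()
  set.seed(7)
  g <- place_neurons(p)
  radii <- c(0.05, 0.1, 0.15, 0.25)
  edges <- lapply(radii, function(r) {
    e <- build_intralayer(g, r)
    paste(e[, 1], e[, 2])
  })
  for (k in seq_along(radii)[-1]) {
    expect_true(all(edges[[k - 1]] %in% edges[[k]]))
  }
})

test_that("fitness follows the inverse-power rule, shuffled as a permutation", {
  p <- network_params(N = 200, beta = 2.5, seed = 5)
  set.seed(5)
  f <- assign_fitness(p)
  sorted <- attr(f, "sorted")
  expect_equal(sorted[25], 4.0, tolerance = 1e-12)  # (25/200)^(-2/3) = 2^2
  expect_equal(sorted[200], 1.0, tolerance = 1e-12)
  expect_true(all(diff(sorted) < 0))  # strictly decreasing in i
  expect_true(all(f > 0))
  expect_equal(sort(f), sort(sorted))  # shuffle is a permutation
  expect_error(network_params(beta = 1), "beta")
})

test_that("fitness tail exponent matches the survival-function power law", {
  # for beta = 2.5 the survival fraction above x scales as x^(1 - beta)
  p <- network_params(N = 10000, beta = 2.5)
  f <- attr(assign_fitness(p), "sorted")
  xs <- exp(seq(log(2), log(20), length.out = 12))
  surv <- vapply(xs, function(x) mean(f > x), numeric(1))
  slope <- coef(lm(log(surv) ~ log(xs)))[2]
  expect_lt(abs(slope - (1 - 2.5)), 0.3)
})

test_that("interlayer score is the distance-discounted fitness product", {
  expect_equal(interlayer_score(1, 1, 0.5, 0.5), 1 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(interlayer_score(2, 3, 0.123, 0), 6)  # delta = 0: distance-free
  s1 <- interlayer_score(1.7, 0.4, 0.3, 1.2)
  s2 <- interlayer_score(1.7, 0.4, 0.15, 1.2)
  expect_equal(s2 / s1, 2^1.2, tolerance = 1e-12)  # halving L scales by 2^delta
  expect_error(interlayer_score(1, 1, 0, 1), "coincident")
})

test_that("threshold calibration hits the target link count exactly", {
  p <- std_net_params()
  set.seed(42)
  g <- place_neurons(p)
  f <- assign_fitness(p)
  cal <- calibrate_theta(f, g, delta = 0.5, kbar_I = 2.0)
  expect_identical(cal$L_target, 200L)
  expect_identical(nrow(cal$pairs), 200L)
  # the returned Theta reproduces the selection under the strict rule
  e <- seq_len(g$N_E); i <- g$N_E + seq_len(g$N_I)
  L <- sqrt(outer(g$x[e], g$x[i], "-")^2 + outer(g$y[e], g$y[i], "-")^2)
  S <- outer(f[e], f[i]) / L^0.5
  expect_identical(sum(S > cal$theta), 200L)
  # a larger threshold can only lose links (monotonicity)
  expect_lte(sum(S > cal$theta * 1.5), 200L)
})

test_that("a maximal target yields the complete bipartite interlayer graph", {
  p <- network_params(N = 20, gamma_I = 0.5, kbar_I = 10, seed = 3)
  set.seed(3)
  g <- place_neurons(p)
  f <- assign_fitness(p)
  cal <- calibrate_theta(f, g, delta = 1, kbar_I = 10)  # L_target = 100 = N_E*N_I
  expect_identical(nrow(cal$pairs), 100L)
  st <- degree_statistics(build_network(p))
  expect_true(all(st$inter_degrees == 10L))
})

test_that("direction assignment is degenerate at xi = 0 and 1, binomial at 0.5", {
  pairs <- cbind(e = 1:50, i = 51:100)
  set.seed(9)
  d1 <- assign_directions(pairs, xi = 1)
  expect_true(all(d1[, "from"] <= 50))  # all E -> I
  d0 <- assign_directions(pairs, xi = 0)
  expect_true(all(d0[, "from"] > 50))   # all I -> E
  # pooled E -> I fraction over many draws sits in the binomial 3-sigma band
  n_rep <- 100
  n_EI <- 0
  for (k in seq_len(n_rep)) {
    d <- assign_directions(pairs, xi = 0.5)
    n_EI <- n_EI + sum(d[, "from"] <= 50)
  }
  n_tot <- n_rep * nrow(pairs)
  expect_lt(abs(n_EI / n_tot - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("the assembled network satisfies its structural contract", {
  p <- std_net_params()
  net <- build_network(p)
  M <- net$M
  expect_true(all(diag(M) == 0))
  eidx <- seq_len(p$N_E)
  expect_identical(M[eidx, eidx], t(M[eidx, eidx]))      # E-E symmetric
  expect_identical(M[-eidx, -eidx], t(M[-eidx, -eidx]))  # I-I symmetric
  # interlayer links: exactly round(N kbar_I / 2), no reciprocal pairs
  EI <- M[eidx, -eidx]; IE <- M[-eidx, eidx]
  expect_identical(sum(EI) + sum(IE), 200L)
  expect_true(all(EI + t(IE) <= 1L))
  # determinism from the seed
  expect_identical(net$M, build_network(p)$M)
  expect_identical(degree_statistics(net)$mean_inter, 2.0)
})

test_that("empty interlayer target leaves all interlayer degrees at zero", {
  p <- std_net_params(kbar_I = 0)
  st <- degree_statistics(build_network(p))
  expect_true(all(st$inter_degrees == 0L))
  expect_identical(st$mean_inter, 0)
})

test_that("interlayer degree dispersion separates the two locality regimes", {
  # heterogeneous (delta = 0.5): heavy-tailed degrees, variance/mean >> 1;
  # local (delta = 10): near-Poisson, variance/mean about 1
  vm <- function(delta, n_nets = 50) {
    degs <- unlist(lapply(seq_len(n_nets), function(k) {
      p <- network_params(N = 200, gamma_I = 0.3, delta = delta,
                          seed = 4000 + k)
      degree_statistics(build_network(p))$inter_degrees
    }))
    var(degs) / mean(degs)
  }
  vm_het <- vm(0.5)
  vm_loc <- vm(10)
  expect_gt(vm_het, 3)
  expect_gt(vm_loc, 0.5)
  expect_lt(vm_loc, 1.5)
  expect_gt(vm_het, vm_loc)  # dispersion decreases with delta
})

test_that("network text round-trip preserves structure", {
  p <- std_net_params(seed = 77)
  net <- build_network(p)
  path <- tempfile(fileext = ".edges")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$M, net$M)
  expect_equal(back$theta, net$theta, tolerance = 1e-12)
  expect_equal(back$fitness, net$fitness, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$geometry$x, net$geometry$x, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".nodes.tsv")))
})
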