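#' Network construction parameters
#'
#' Bundles all parameters that govern the two-layered network: total size,
#' layer split, the intralayer random-geometric distance threshold, and the
#' vertex-fitness interlayer model (fitness exponent, locality exponent,
#' direction probability, target mean interlayer degree).
#'
#' @param N Total number of neurons (>= 2).
#' @param gamma_I Fraction of inhibitory neurons, in \[0, 1\]. The number of
#'   inhibitory neurons is `N_I = round(N * gamma_I)`; neurons `1..N_E` are
#'   excitatory and `N_E+1..N` inhibitory.
#' @param R_th Intralayer connection radius (unit-square length units). Two
#'   same-layer neurons are linked bidirectionally iff their Euclidean
#'   distance is strictly less than `R_th`.
#' @param beta Fitness exponent (> 1); fitness values before shuffling are
#'   `(i/N)^(1/(1-beta))` for `i = 1..N`.
#' @param delta Interlayer locality exponent (>= 0). Small values give a
#'   heterogeneous, scale-free-like interlayer degree distribution; large
#'   values restrict links to spatially adjacent pairs and give a
#'   Poisson-like distribution.
#' @param xi Probability that a qualifying interlayer link is directed from
#'   the excitatory to the inhibitory layer (an excitatory axon), in \[0, 1\].
#' @param kbar_I Target mean number of interlayer connections per neuron;
#'   the calibrated threshold realizes exactly `round(N * kbar_I / 2)` links.
#' @param seed Integer RNG seed used by [build_network()].
#'
#' @return An object of class `"fhn_net_params"` (a named list).
#' @examples
#' p <- network_params(N = 200, gamma_I = 0.2)
#' p$N_E  # 160 excitatory neurons
#' @export
network_params <- function(N = 200, gamma_I = 0.2, R_th = 0.126, beta = 2.5,
                           delta = 0.5, xi = 0.5, kbar_I = 2.0, seed = 1L) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 2, N == round(N))
  stopifnot(gamma_I >= 0, gamma_I <= 1)
  stopifnot(R_th > 0)
  if (beta <= 1) {
    stop("`beta` must exceed 1: the fitness exponent 1/(1 - beta) is singular at beta = 1 ",
         "and the fitness distribution loses its decreasing tail for beta <= 1.")
  }
  stopifnot(delta >= 0, xi >= 0, xi <= 1, kbar_I >= 0)
  N <- as.integer(N)
  N_I <- as.integer(round(N * gamma_I))
  N_E <- N - N_I
  if (round(N * kbar_I / 2) > N_E * N_I) {
    stop("interlayer degree target unachievable: round(N*kbar_I/2) = ",
         round(N * kbar_I / 2), " exceeds N_E*N_I = ", N_E * N_I)
  }
  structure(list(N = N, gamma_I = gamma_I, N_E = N_E, N_I = N_I,
                 R_th = R_th, beta = beta, delta = delta, xi = xi,
                 kbar_I = kbar_I, seed = as.integer(seed)),
            class = "fhn_net_params")
}

#' Place neurons uniformly in the unit square
#'
#' Draws independent uniform positions in \[0,1\]^2 and assigns layer labels
#' by index: neurons `1..N_E` are excitatory (`"E"`), the rest inhibitory
#' (`"I"`). Uses R's current RNG stream; seed it with [set.seed()] for
#' reproducibility (done by [build_network()]).
#'
#' @param params An [network_params()] object.
#' @return An object of class `"fhn_geometry"`: list with `x`, `y`, `layer`
#'   (factor with levels `E`, `I`), `N_E`, `N_I`.
#' @export
place_neurons <- function(params) {
  stopifnot(inherits(params, "fhn_net_params"))
  if (params$N_I == 0L || params$N_E == 0L) {
    warning("degenerate single-layer network: N_E = ", params$N_E,
            ", N_I = ", params$N_I)
  }
  structure(list(
    x = stats::runif(params$N),
    y = stats::runif(params$N),
    layer = factor(rep(c("E", "I"), c(params$N_E, params$N_I)),
                   levels = c("E", "I")),
    N_E = params$N_E, N_I = params$N_I
  ), class = "fhn_geometry")
}

#' Build intralayer random-geometric edges
#'
#' Connects every pair of same-layer neurons whose Euclidean distance in the
#' plane is strictly less than `R_th`. Edges are undirected; no cross-layer
#' edges are created here.
#'
#' @param geometry An `"fhn_geometry"` object.
#' @param R_th Distance threshold (> 0).
#' @return Two-column integer matrix of undirected edges (`i < j`), one row
#'   per edge; zero rows if none.
#' @export
build_intralayer <- function(geometry, R_th) {
  stopifnot(inherits(geometry, "fhn_geometry"), R_th > 0)
  N <- length(geometry$x)
  d <- as.matrix(stats::dist(cbind(geometry$x, geometry$y)))
  same <- outer(geometry$layer, geometry$layer, "==")
  adj <- d < R_th & same
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  which(adj, arr.ind = TRUE, useNames = FALSE)
}

#' Assign vertex fitness values
#'
#' Deterministic fitness `f_i = (i/N)^(1/(1-beta))` for `i = 1..N` (strictly
#' decreasing in `i` for `beta > 1`, with `f_N = 1`), then shuffled uniformly
#' at random across neurons so that high-fitness vertices are well mixed over
#' both layers.
#'
#' @param params An [network_params()] object (`beta > 1` enforced there).
#' @return Numeric vector of length `N`, all values positive. The pre-shuffle
#'   values are available as `attr(, "sorted")`.
#' @examples
#' f <- assign_fitness(network_params(N = 200, beta = 2.5, seed = 1))
#' sort(f)[1]  # smallest value is f_N = 1
#' @export
assign_fitness <- function(params) {
  stopifnot(inherits(params, "fhn_net_params"))
  f0 <- ((seq_len(params$N)) / params$N)^(1 / (1 - params$beta))
  f <- sample(f0)
  attr(f, "sorted") <- f0
  f
}

#' Interlayer connection score
#'
#' The vertex-fitness score `f_i * f_j / L_ij^delta` for a candidate
#' interlayer pair at planar distance `L_ij`. A pair is linked iff the
#' calibrated threshold `Theta` is strictly smaller than its score.
#'
#' @param f_i,f_j Fitness values (positive).
#' @param L_ij Planar Euclidean distance (> 0); coincident placement is an
#'   error, positions must be redrawn.
#' @param delta Locality exponent (>= 0).
#' @return Positive numeric score (vectorized over its arguments).
#' @export
interlayer_score <- function(f_i, f_j, L_ij, delta) {
  if (any(L_ij <= 0)) {
    stop("coincident neuron placement (L_ij = 0): regenerate positions")
  }
  f_i * f_j / L_ij^delta
}

#' Calibrate the interlayer connectivity threshold
#'
#' Finds the threshold `Theta` such that exactly `L_target` excitatory-
#' inhibitory pairs have score strictly above it, by order statistics of all
#' `N_E * N_I` pair scores: `Theta` is placed halfway between the
#' `L_target`-th and `(L_target+1)`-th largest scores. Ties at the cut are
#' broken by pair index order (scores are perturbed by nothing; `sort` with
#' index tie-break keeps the selection deterministic).
#'
#' @param fitness Fitness vector of length `N` (see [assign_fitness()]).
#' @param geometry An `"fhn_geometry"` object.
#' @param delta Locality exponent.
#' @param kbar_I Target mean interlayer degree; the target link count is
#'   `round(N * kbar_I / 2)`.
#' @return List with `theta`, the selected pair index matrix `pairs`
#'   (columns `e`, `i` of neuron indices), and `L_target`.
#' @export
calibrate_theta <- function(fitness, geometry, delta, kbar_I) {
  N_E <- geometry$N_E; N_I <- geometry$N_I
  N <- N_E + N_I
  L_target <- round(N * kbar_I / 2)
  stopifnot(L_target <= N_E * N_I)
  e_idx <- seq_len(N_E)
  i_idx <- N_E + seq_len(N_I)
  L <- sqrt(outer(geometry$x[e_idx], geometry$x[i_idx], "-")^2 +
            outer(geometry$y[e_idx], geometry$y[i_idx], "-")^2)
  if (any(L == 0)) {
    stop("coincident neuron placement (L_ij = 0): regenerate positions")
  }
  S <- outer(fitness[e_idx], fitness[i_idx]) / L^delta
  if (L_target == 0L) {
    return(list(theta = max(S), pairs = cbind(e = integer(0), i = integer(0)),
                L_target = 0L))
  }
  ord <- order(S, decreasing = TRUE)  # ties broken by pair (column-major) index
  sel <- ord[seq_len(L_target)]
  s_in <- S[sel[L_target]]
  theta <- if (L_target < length(S)) {
    s_out <- S[ord[L_target + 1L]]
    (s_in + s_out) / 2
  } else {
    s_in / 2  # complete bipartite: any Theta below the minimum score
  }
  pairs <- cbind(e = e_idx[(sel - 1L) %% N_E + 1L],
                 i = i_idx[(sel - 1L) %/% N_E + 1L])
  list(theta = theta, pairs = pairs, L_target = as.integer(L_target))
}

#' Assign directions to interlayer links
#'
#' For each qualifying excitatory-inhibitory pair an independent uniform
#' `r` is drawn; if `r <= xi` the link is directed E -> I (excitatory axon),
#' otherwise I -> E (inhibitory axon). Exactly one directed edge per pair.
#'
#' @param pairs Two-column matrix (`e`, `i`) of neuron indices.
#' @param xi Probability of the E -> I direction.
#' @return Two-column integer matrix with columns `from`, `to`.
#' @export
assign_directions <- function(pairs, xi) {
  stopifnot(xi >= 0, xi <= 1)
  n <- nrow(pairs)
  if (n == 0L) return(cbind(from = integer(0), to = integer(0)))
  to_I <- stats::runif(n) <= xi
  cbind(from = ifelse(to_I, pairs[, "e"], pairs[, "i"]),
        to   = ifelse(to_I, pairs[, "i"], pairs[, "e"]))
}

#' Generate a two-layered excitatory/inhibitory network
#'
#' Full construction pipeline: uniform placement in the unit square,
#' undirected random-geometric intralayer edges (distance `< R_th`), vertex
#' fitness assignment, threshold calibration to the target interlayer link
#' count, and random direction assignment. Fully reproducible from
#' `params$seed`.
#'
#' @param params An [network_params()] object.
#' @return An object of class `"fhn_network"`: list with the `N x N` binary
#'   coupling matrix `M` (`M[j, i] = 1` means a connection from presynaptic
#'   `j` to postsynaptic `i`; intralayer links appear in both orientations),
#'   `geometry`, `fitness`, `theta`, `params`, the undirected
#'   `intra_edges` and directed `inter_edges` matrices.
#' @examples
#' net <- build_network(network_params(N = 100, seed = 42))
#' sum(net$M[1:net$params$N_E, -(1:net$params$N_E)]) +
#'   sum(net$M[-(1:net$params$N_E), 1:net$params$N_E])  # == round(N*kbar_I/2)
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "fhn_net_params"))
  set.seed(params$seed)
  geometry <- place_neurons(params)
  # coincident placements (probability zero, but guarded): redraw
  for (tries in 1:100) {
    d <- stats::dist(cbind(geometry$x, geometry$y))
    if (all(d > 0)) break
    geometry <- place_neurons(params)
  }
  intra <- build_intralayer(geometry, params$R_th)
  fitness <- assign_fitness(params)
  cal <- calibrate_theta(fitness, geometry, params$delta, params$kbar_I)
  inter <- assign_directions(cal$pairs, params$xi)

  N <- params$N
  M <- matrix(0L, N, N)
  if (nrow(intra) > 0) {
    M[intra] <- 1L
    M[intra[, c(2, 1), drop = FALSE]] <- 1L
  }
  if (nrow(inter) > 0) M[inter] <- 1L
  structure(list(M = M, geometry = geometry, fitness = fitness,
                 theta = cal$theta, params = params,
                 intra_edges = intra, inter_edges = inter),
            class = "fhn_network")
}

#' @export
print.fhn_network <- function(x, ...) {
  p <- x$params
  cat(sprintf("Two-layered FHN network: N = %d (E = %d, I = %d)\n",
              p$N, p$N_E, p$N_I))
  cat(sprintf("  intralayer edges: %d (R_th = %g)\n", nrow(x$intra_edges), p$R_th))
  cat(sprintf("  interlayer links: %d directed (kbar_I = %g, Theta = %.4g, delta = %g, xi = %g)\n",
              nrow(x$inter_edges), p$kbar_I, x$theta, p$delta, p$xi))
  invisible(x)
}

#' Degree statistics of a layered network
#'
#' Intralayer degrees count undirected same-layer neighbours; the interlayer
#' degree of a neuron counts its interlayer links regardless of direction
#' (in- plus out-links; each link contributes once to each endpoint).
#'
#' @param network An `"fhn_network"` object.
#' @return List with `mean_intra_E`, `mean_intra_I`, `mean_intra_pooled`,
#'   `mean_inter` (equals `2 * links / N`), `inter_degrees` (length-`N`
#'   integer vector) and `inter_hist` (a [table()] of interlayer degrees).
#' @export
degree_statistics <- function(network) {
  stopifnot(inherits(network, "fhn_network"))
  p <- network$params
  N <- p$N
  intra_deg <- tabulate(c(network$intra_edges), nbins = N)
  inter_deg <- tabulate(c(network$inter_edges), nbins = N)
  eidx <- seq_len(p$N_E)
  list(
    mean_intra_E = if (p$N_E > 0) mean(intra_deg[eidx]) else NA_real_,
    mean_intra_I = if (p$N_I > 0) mean(intra_deg[-eidx]) else NA_real_,
    mean_intra_pooled = mean(intra_deg),
    mean_inter = 2 * nrow(network$inter_edges) / N,
    inter_degrees = inter_deg,
    inter_hist = table(inter_deg)
  )
}

#' Ensemble-mean intralayer degree at a given radius
#'
#' The calibration statistic behind the choice of `R_th`: the mean number of
#' intralayer connections per neuron of the excitatory (majority) layer,
#' averaged over an ensemble of independently generated networks at
#' `gamma_I` (0.1 for the reference calibration). Only positions are needed,
#' so the fitness/interlayer machinery is skipped.
#'
#' @param R_th Distance threshold.
#' @param n_networks Ensemble size (>= 1).
#' @param N,gamma_I Network size and inhibitory fraction.
#' @param seed Integer seed for the ensemble.
#' @param pooled If `TRUE`, average over all neurons of both layers instead
#'   of the excitatory layer only.
#' @return Ensemble-mean intralayer degree (scalar).
#' @export
mean_intralayer_degree <- function(R_th, n_networks = 200, N = 200,
                                   gamma_I = 0.1, seed = 1L, pooled = FALSE) {
  N_I <- round(N * gamma_I); N_E <- N - N_I
  set.seed(seed)
  acc <- 0
  for (k in seq_len(n_networks)) {
    x <- stats::runif(N); y <- stats::runif(N)
    d <- as.matrix(stats::dist(cbind(x, y)))
    lay <- rep(1:2, c(N_E, N_I))
    adj <- d < R_th & outer(lay, lay, "==")
    diag(adj) <- FALSE
    deg <- rowSums(adj)
    acc <- acc + if (pooled) mean(deg) else mean(deg[seq_len(N_E)])
  }
  acc / n_networks
}

#' Calibrate the intralayer radius to a target mean degree
#'
#' Bisects `R_th` so that the ensemble-mean intralayer degree (see
#' [mean_intralayer_degree()]) matches `k_target`. The same position
#' ensemble (common random numbers, fixed by `seed`) is reused at every
#' bisection evaluation, which makes the objective exactly monotone in
#' `R_th` and the bisection well-posed despite the stochastic ensemble.
#'
#' @param k_target Target mean intralayer degree (default 8.0).
#' @param n_networks Networks per ensemble evaluation (>= 200 recommended).
#' @param N,gamma_I Network size and inhibitory fraction (reference
#'   calibration: N = 200, gamma_I = 0.1).
#' @param seed Ensemble seed.
#' @param interval Search bracket for `R_th`.
#' @param tol Bisection tolerance on `R_th`.
#' @param pooled Passed to [mean_intralayer_degree()].
#' @return The calibrated `R_th` (scalar).
#' @export
calibrate_rth <- function(k_target = 8.0, n_networks = 200, N = 200,
                          gamma_I = 0.1, seed = 1L,
                          interval = c(0.05, 0.3), tol = 1e-4,
                          pooled = FALSE) {
  f <- function(R) mean_intralayer_degree(R, n_networks, N, gamma_I,
                                          seed = seed, pooled = pooled) - k_target
  stats::uniroot(f, interval = interval, tol = tol)$root
}
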