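#' Write a layered network to plain text
#'
#' Edge-list format: header comment lines (`# key value`) recording `N`,
#' `gamma_I`, `seed`, `theta`, followed by one line per edge as
#' `"j i directed|undirected"` (undirected intralayer edges once, with
#' `j < i`). A companion delimited table `<path>.nodes.tsv` stores the
#' per-neuron index, position, layer label, and fitness.
#'
#' @param network An `"fhn_network"` object.
#' @param path Output path for the edge list.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  p <- network$params
  hdr <- c(sprintf("# N %d", p$N),
           sprintf("# gamma_I %.10g", p$gamma_I),
           sprintf("# seed %d", p$seed),
           sprintf("# theta %.15g", network$theta))
  intra <- network$intra_edges
  inter <- network$inter_edges
  lines <- c(hdr,
             if (nrow(intra)) sprintf("%d %d undirected", intra[, 1], intra[, 2]),
             if (nrow(inter)) sprintf("%d %d directed", inter[, 1], inter[, 2]))
  writeLines(lines, path)
  g <- network$geometry
  utils::write.table(
    data.frame(index = seq_len(p$N), x = g$x, y = g$y,
               layer = as.character(g$layer), fitness = network$fitness),
    paste0(path, ".nodes.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a layered network written by [write_network()]
#'
#' Restores the coupling matrix, geometry, fitness and threshold. The
#' construction parameters beyond those in the header are not stored and
#' are returned as recorded defaults.
#'
#' @param path Path to the edge list (the `.nodes.tsv` companion must sit
#'   alongside).
#' @return An `"fhn_network"` object.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)[1]
    as.numeric(sub(paste0("^# ", key, " "), "", ln))
  }
  N <- as.integer(get("N")); gamma_I <- get("gamma_I")
  seed <- as.integer(get("seed")); theta <- get("theta")
  nodes <- utils::read.table(paste0(path, ".nodes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, " ", fixed = TRUE)
  from <- vapply(parts, function(z) as.integer(z[1]), integer(1))
  to <- vapply(parts, function(z) as.integer(z[2]), integer(1))
  kind <- vapply(parts, `[`, character(1), 3)
  undir <- kind == "undirected"
  intra <- cbind(from[undir], to[undir])
  inter <- cbind(from = from[!undir], to = to[!undir])
  N_I <- sum(nodes$layer == "I"); N_E <- N - N_I
  params <- network_params(N = N, gamma_I = gamma_I, seed = seed)
  geometry <- structure(list(x = nodes$x, y = nodes$y,
                             layer = factor(nodes$layer, levels = c("E", "I")),
                             N_E = N_E, N_I = N_I),
                        class = "fhn_geometry")
  M <- matrix(0L, N, N)
  if (nrow(intra)) {
    M[intra] <- 1L
    M[intra[, c(2, 1), drop = FALSE]] <- 1L
  }
  if (nrow(inter)) M[inter] <- 1L
  structure(list(M = M, geometry = geometry, fitness = nodes$fitness,
                 theta = theta, params = params,
                 intra_edges = intra, inter_edges = inter),
            class = "fhn_network")
}

#' Write a trajectory container
#'
#' Binary array container (RDS) embedding the trajectory together with its
#' metadata: dynamics parameters, seed, and a hash of the generating
#' network's edge sets.
#'
#' @param trajectory An `"fhn_trajectory"` object.
#' @param path Output path.
#' @param network Optional generating network; stores an edge-set hash.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, network = NULL) {
  meta <- list(params = trajectory$params,
               network_hash = if (!is.null(network)) {
                 sum(network$M * seq_along(network$M)) %% 2^31
               })
  saveRDS(list(trajectory = trajectory, meta = meta), path)
  invisible(path)
}

#' Read a trajectory container written by [write_trajectory()]
#' @param path Path to the container.
#' @return An `"fhn_trajectory"` object with attribute `meta`.
#' @export
read_trajectory <- function(path) {
  obj <- readRDS(path)
  traj <- obj$trajectory
  attr(traj, "meta") <- obj$meta
  traj
}

#' Export a spike raster as delimited text
#'
#' One line per spike: neuron index and spike time, tab-separated.
#'
#' @param raster An `"fhn_raster"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  df <- data.frame(
    neuron = rep(seq_along(raster), lengths(raster)),
    time = unlist(raster, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export coherence results as a delimited table
#'
#' Per-neuron rows (index, layer, `T_i`) followed by a summary row holding
#' the population and layer averages.
#'
#' @param coherence An `"fhn_coherence"` object.
#' @param layer Layer labels for the neurons.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coherence <- function(coherence, layer, path) {
  df <- data.frame(neuron = seq_along(coherence$T_i),
                   layer = as.character(layer),
                   T_i = coherence$T_i)
  summary_row <- data.frame(neuron = NA_integer_, layer = "mean",
                            T_i = coherence$T_bar)
  utils::write.table(rbind(df, summary_row), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cat(sprintf("# T_bar %.10g T_bar_E %.10g T_bar_I %.10g\n",
              coherence$T_bar, coherence$T_bar_E, coherence$T_bar_I),
      file = path, append = TRUE)
  invisible(path)
}

#' Read a sweep specification from a YAML config file
#'
#' Structured text configuration with top-level keys `grids` (named lists
#' of values), optional `net_params`, `dyn_params`, `coherence`
#' (field-value maps overriding the defaults), `n_realizations` and
#' `base_seed`. Note that a bare `N` key parses as a YAML boolean; quote it
#' (`"N": 200`).
#'
#' @param path Path to the YAML file.
#' @return An [sweep_spec()] object.
#' @export
read_sweep_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$grids))
  np <- do.call(network_params, c(cfg$net_params))
  dp <- do.call(dynamics_params, c(cfg$dyn_params))
  cc <- do.call(coherence_config, c(cfg$coherence))
  sweep_spec(grids = lapply(cfg$grids, unlist),
             net_params = np, dyn_params = dp, coh_config = cc,
             n_realizations = cfg$n_realizations %||% 50,
             base_seed = cfg$base_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sweep result with a metadata header
#'
#' Delimited table preceded by `#`-prefixed header lines recording the
#' fixed parameters and base seed.
#'
#' @param result An `"fhn_sweep_result"`.
#' @param spec The generating [sweep_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_result <- function(result, spec, path) {
  fixed <- c(unclass(spec$net_params), unclass(spec$dyn_params))
  fixed <- fixed[setdiff(names(fixed), names(spec$grids))]
  hdr <- c(sprintf("# base_seed %d", spec$base_seed),
           sprintf("# n_realizations %d", spec$n_realizations),
           sprintf("# %s %s", names(fixed), vapply(fixed, format, character(1))))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(result, path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(path)
}
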