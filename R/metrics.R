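#' Fraction of communicative players
#' @param state A state tibble (see [random_state()]).
#' @return `count(label == "C") / N`; phases are ignored.
#' @export
communicative_fraction <- function(state) {
  if (nrow(state) == 0) abort("empty state.")
  mean(state$label == "C")
}

#' Kuramoto order parameter
#'
#' `rho = |sum_j exp(i phi_j)| / N`: 1 for full phase coherence, 0 for
#' complete disorder (e.g. phases uniformly spread over the roots of unity).
#'
#' @param state A state tibble with a `phase` column (radians).
#' @return A value in `[0, 1]`.
#' @export
order_parameter <- function(state) {
  if (nrow(state) == 0) abort("empty state.")
  Mod(mean(exp(1i * state$phase)))
}

#' Per-community order parameters
#'
#' The Kuramoto modulus evaluated inside each community with its own size
#' `N_m`; a singleton community is always perfectly coherent.
#'
#' @param state A state tibble.
#' @param communities A tibble `(node, community)` covering every node.
#' @return A tibble `(community, n, rho_m)` sorted by community id.
#' @export
community_order <- function(state, communities) {
  communities <- as_tibble(communities)
  if (!all(state$node %in% communities$node)) {
    abort("every node needs a community assignment.")
  }
  state %>%
    left_join(communities, by = "node") %>%
    group_by(.data$community) %>%
    summarise(n = dplyr::n(),
              rho_m = Mod(mean(exp(1i * .data$phase))), .groups = "drop") %>%
    arrange(.data$community)
}

as_trace_matrix <- function(traces) {
  if (is_tibble(traces) || is.data.frame(traces)) {
    traces <- traces[setdiff(names(traces), c("step", "t"))]
    traces <- as.matrix(traces)
  }
  if (!is.matrix(traces)) abort("`traces` must be a T x M matrix or data frame.")
  storage.mode(traces) <- "double"
  traces
}

#' Chimera-like index
#'
#' Time average of the across-community sample variance of the community
#' order parameters: per sampled step,
#' `sigma_chi = sum_m (rho_m - mean_m rho_m)^2 / (M - 1)`, and
#' `chi = mean_t sigma_chi`. Zero when communities are always equally
#' coherent; maximal, `M / (4 (M - 1))`, when half the communities sit at
#' `rho_m = 1` and half at 0 for all time (0.3 for M = 6).
#'
#' @param traces A `T x M` matrix (rows = sampled steps, columns =
#'   communities) of `rho_m` values; a tibble from
#'   [community_order_series()] also works (a `step` column is dropped).
#' @return The scalar index `chi`.
#' @export
chimera_index <- function(traces) {
  x <- as_trace_matrix(traces)
  if (ncol(x) < 2) abort("chimera index needs M >= 2 communities.")
  mu <- rowMeans(x)
  sigma_chi <- rowSums((x - mu)^2) / (ncol(x) - 1)
  mean(sigma_chi)
}

#' Metastability index
#'
#' Community average of the temporal sample variance of each community's
#' order-parameter trace:
#' `sigma_met = sum_t (rho_m(t) - mean_t rho_m)^2 / (T - 1)`, and
#' `lambda = mean_m sigma_met`. Zero for communities pinned at any constant
#' coherence; approaches 1/4 in the large-T limit for communities spending
#' equal time fully synchronized and fully disordered.
#'
#' @inheritParams chimera_index
#' @return The scalar index `lambda`.
#' @export
metastability_index <- function(traces) {
  x <- as_trace_matrix(traces)
  if (nrow(x) < 2) abort("metastability index needs T >= 2 sampled steps.")
  mean(apply(x, 2, var))
}

#' Chimera summary of a set of community traces
#'
#' @inheritParams chimera_index
#' @return An `ek_chimera` list: `chi`, `lambda`, the per-step `sigma_chi`
#'   trace and per-community `sigma_met` vector.
#' @export
chimera_summary <- function(traces) {
  x <- as_trace_matrix(traces)
  if (ncol(x) < 2) abort("chimera summary needs M >= 2 communities.")
  if (nrow(x) < 2) abort("chimera summary needs T >= 2 sampled steps.")
  mu <- rowMeans(x)
  sigma_chi <- rowSums((x - mu)^2) / (ncol(x) - 1)
  sigma_met <- apply(x, 2, var)
  structure(list(chi = mean(sigma_chi), lambda = mean(sigma_met),
                 sigma_chi = sigma_chi, sigma_met = sigma_met,
                 M = ncol(x), T = nrow(x)),
            class = "ek_chimera")
}

#' @export
print.ek_chimera <- function(x, ...) {
  cat(sprintf("# ek_chimera: M=%d, T=%d, chi=%.6g (max %.3g), lambda=%.6g\n",
              x$M, x$T, x$chi, x$M / (4 * (x$M - 1)), x$lambda))
  invisible(x)
}

#' @export
glance.ek_chimera <- function(x, ...) {
  tibble(chi = x$chi, lambda = x$lambda, M = x$M, n_steps = x$T,
         chi_max = x$M / (4 * (x$M - 1)))
}

#' @export
tidy.ek_chimera <- function(x, ...) {
  tibble(community = seq_len(x$M), sigma_met = as.numeric(x$sigma_met))
}

#' Detect communities with the constant Potts model
#'
#' Delegates to the Leiden algorithm (igraph) optimizing the constant Potts
#' model, with the settings used throughout: resolution 0.1,
#' refinement randomness `beta = 0.01`, 2 iterations. igraph's Leiden works on
#' undirected graphs, so the directed weighted graph is collapsed to a
#' weighted undirected one by summing reciprocal weights first (message).
#'
#' @param g An [ek_graph()].
#' @param resolution CPM resolution parameter.
#' @param beta Leiden refinement randomness.
#' @param n_iterations Leiden iterations.
#' @param seed Integer seed for the (stochastic) algorithm.
#' @return A tibble `(node, community)` with integer community ids 1..M.
#' @export
detect_communities <- function(g, resolution = 0.1, beta = 0.01,
                               n_iterations = 2, seed = 1L) {
  assert_ek_graph(g)
  ig <- as_igraph(g)
  if (igraph::is_directed(ig)) {
    inform("collapsing directed graph to weighted undirected (reciprocal weights summed) for Leiden/CPM")
    ig <- igraph::as_undirected(ig, mode = "collapse",
                                edge.attr.comb = list(weight = "sum"))
  }
  set.seed(seed)
  cl <- igraph::cluster_leiden(ig, objective_function = "CPM",
                               resolution = resolution, beta = beta,
                               n_iterations = n_iterations,
                               weights = igraph::E(ig)$weight)
  tibble(node = igraph::V(ig)$name,
         community = as.integer(igraph::membership(cl)))
}

#' Read / write a community assignment TSV
#' @param path A two-column TSV `node<TAB>community`.
#' @return A tibble `(node, community)`.
#' @export
load_communities <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  names(df) <- c("node", "community")
  as_tibble(df)
}

#' @rdname load_communities
#' @param communities A tibble `(node, community)`.
#' @export
write_communities <- function(communities, path) {
  utils::write.table(as.data.frame(communities)[c("node", "community")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Community order-parameter time series of a run
#'
#' @param sim An `ek_sim` from [run_simulation()].
#' @param communities A tibble `(node, community)`.
#' @return A wide tibble: `step` plus one `rho_m` column per community
#'   (`rho_1`, `rho_2`, ...).
#' @export
community_order_series <- function(sim, communities) {
  communities <- as_tibble(communities)
  idx <- match(sim$nodes, communities$node)
  if (anyNA(idx)) abort("every node needs a community assignment.")
  comm <- communities$community[idx]
  ids <- sort(unique(comm))
  phases_rad <- 2 * pi * sim$phases / sim$params$m
  z <- exp(1i * phases_rad)
  out <- lapply(ids, function(mm) {
    cols <- comm == mm
    Mod(rowMeans(z[, cols, drop = FALSE]))
  })
  names(out) <- paste0("rho_", ids)
  dplyr::bind_cols(tibble(step = sim$metrics$step), as_tibble(out))
}

# ---- game censuses over the interaction graph -------------------------------

# Mixed-pair game name as a function of the phase-index difference d = 0..m-1
# (f is even, so only the cyclic difference matters).
mixed_game_by_dk <- function(params, tol = 1e-9) {
  vapply(seq_len(params$m) - 1L, function(d) {
    f <- coupling(2 * pi * d / params$m)
    classify_rstp(R = params$B0 - params$c,
                  S = 2 * params$alpha * params$beta0 * f - params$c,
                  T = 2 * (1 - params$alpha) * params$beta0 * f,
                  P = 0, tol = tol)$name
  }, character(1))
}

#' Weighted census of game types across all edges
#'
#' Classifies every directed edge's hypothetical-switch game (CC pairs as
#' `"cooperation"`, NN pairs as `"neutral"`) and accumulates edge weights.
#'
#' @param g An [ek_graph()] interaction graph.
#' @param state A state tibble.
#' @param params An [ek_params()].
#' @return A tibble `(game, weight, fraction)` with fractions of total weight.
#' @export
game_census <- function(g, state, params) {
  assert_ek_graph(g)
  nodes <- graph_nodes(g)
  state <- as_state_tibble(state, nodes, params$m)
  hi <- match(g$to, nodes)
  ti <- match(g$from, nodes)
  games <- edge_game_types(state$label[hi] == "C", state$k[hi],
                           state$label[ti] == "C", state$k[ti],
                           mixed_game_by_dk(params), params$m)
  agg <- rowsum(as.numeric(g$weight), games)
  tibble(game = rownames(agg), weight = as.numeric(agg[, 1])) %>%
    mutate(fraction = .data$weight / sum(.data$weight)) %>%
    arrange(dplyr::desc(.data$weight), .data$game)
}

edge_game_types <- function(head_C, head_k, tail_C, tail_k, mixed_tab, m) {
  games <- character(length(head_C))
  both_c <- head_C & tail_C
  both_n <- !head_C & !tail_C
  mixed <- !(both_c | both_n)
  games[both_c] <- "cooperation"
  games[both_n] <- "neutral"
  if (any(mixed)) {
    d <- (head_k[mixed] - tail_k[mixed]) %% m
    games[mixed] <- mixed_tab[d + 1L]
  }
  games
}

plurality_from_weights <- function(games, weights) {
  agg <- rowsum(weights, games)
  w <- agg[, 1]
  # deterministic alphabetical tie-break on the game name
  names(w)[order(-w, names(w))][1]
}

#' Plurality game type of a state
#'
#' The weight-heaviest game type across all edges. A fully communicative
#' population is labelled `"all-C"` and a fully non-communicative one
#' `"all-N"` regardless of phases. Ties break alphabetically on the name.
#'
#' @param census A tibble from [game_census()].
#' @param state The state the census was computed from.
#' @return A label: a game name, `"all-C"` or `"all-N"`.
#' @export
plurality_game <- function(census, state) {
  fc <- communicative_fraction(state)
  if (fc == 1) return("all-C")
  if (fc == 0) return("all-N")
  plurality_from_weights(census$game, census$weight)
}

#' Plurality mixed game type
#'
#' As [plurality_game()] but restricted to games between mixed C/N pairs;
#' a mixed population whose edges happen never to join a C with an N yields
#' `"none"`.
#'
#' @inheritParams plurality_game
#' @return A label: a mixed game name, `"all-C"`, `"all-N"` or `"none"`.
#' @export
plurality_mixed_game <- function(census, state) {
  fc <- communicative_fraction(state)
  if (fc == 1) return("all-C")
  if (fc == 0) return("all-N")
  mixed <- census[!census$game %in% c("cooperation", "neutral"), , drop = FALSE]
  if (nrow(mixed) == 0 || sum(mixed$weight) == 0) return("none")
  plurality_from_weights(mixed$game, mixed$weight)
}

#' Per-sample game metrics of a run
#'
#' Classifies every edge at every sampled step and records the plurality and
#' plurality-mixed game labels.
#'
#' @param sim An `ek_sim`.
#' @return The run's metrics tibble extended with `plurality_game` and
#'   `plurality_mixed_game` columns.
#' @export
sim_game_metrics <- function(sim) {
  g <- sim$graph
  nodes <- sim$nodes
  hi <- match(g$to, nodes)
  ti <- match(g$from, nodes)
  w <- as.numeric(g$weight)
  mixed_tab <- mixed_game_by_dk(sim$params)
  m <- sim$params$m
  nsamp <- nrow(sim$metrics)
  plur <- character(nsamp)
  plur_mixed <- character(nsamp)
  for (i in seq_len(nsamp)) {
    lab <- sim$labels[i, ] == 1
    fc <- mean(lab)
    if (fc == 1) { plur[i] <- "all-C"; plur_mixed[i] <- "all-C"; next }
    if (fc == 0) { plur[i] <- "all-N"; plur_mixed[i] <- "all-N"; next }
    kk <- sim$phases[i, ]
    games <- edge_game_types(lab[hi], kk[hi], lab[ti], kk[ti], mixed_tab, m)
    plur[i] <- plurality_from_weights(games, w)
    is_mixed <- !(games %in% c("cooperation", "neutral"))
    plur_mixed[i] <- if (!any(is_mixed)) "none" else
      plurality_from_weights(games[is_mixed], w[is_mixed])
  }
  dplyr::bind_cols(sim$metrics,
                   tibble(plurality_game = plur, plurality_mixed_game = plur_mixed))
}
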