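#' Random initial population state
#'
#' Each player independently draws one of the `2 m` strategies (label C or N,
#' phase index `0..m-1`) uniformly — the initial condition of every run.
#'
#' @param nodes Character vector of node labels (or a single count, in which
#'   case nodes are `"0" ... "N-1"`).
#' @param m Number of discrete phases.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return A state tibble with columns `node`, `label` (`"C"`/`"N"`), `k`
#'   (phase index) and `phase` (radians).
#' @export
random_state <- function(nodes, m = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(nodes) && length(nodes) == 1) {
    nodes <- as.character(seq_len(nodes) - 1L)
  }
  N <- length(nodes)
  idx <- floor(runif(N) * 2 * m)
  idx[idx >= 2 * m] <- 2 * m - 1
  k <- as.integer(idx %% m)
  tibble(node = nodes,
         label = ifelse(idx < m, "C", "N"),
         k = k,
         phase = 2 * pi * k / m)
}

as_state_tibble <- function(state, nodes, m) {
  state <- as_tibble(state)
  if (!all(c("node", "label", "k") %in% names(state))) {
    abort("a state needs columns `node`, `label`, `k`.")
  }
  if (!setequal(state$node, nodes)) abort("state nodes do not match the graph.")
  state <- state[match(nodes, state$node), ]
  if (any(state$k < 0 | state$k >= m)) abort("phase indices must lie in [0, m-1].")
  state$phase <- 2 * pi * state$k / m
  state
}

edges_indexed <- function(g) {
  nodes <- graph_nodes(g)
  list(tail = match(g$from, nodes) - 1L,
       head = match(g$to, nodes) - 1L,
       w = as.integer(g$weight))
}

#' Total payoff of every node under a fixed state
#'
#' Full (non-incremental) recomputation: the payoff of node `i` is the sum
#' over in-edges `(j -> i)` of `w_ij * edge_payoff(state_i, state_j)`;
#' self-loops contribute at phase difference zero with the node's own label.
#' Total (not degree-averaged) payoff feeds the exponential fitness.
#'
#' @param g An [ek_graph()] interaction graph.
#' @param state A state tibble (see [random_state()]).
#' @param params An [ek_params()].
#' @return A tibble `(node, payoff, fitness)`.
#' @export
node_payoffs <- function(g, state, params) {
  assert_ek_graph(g)
  nodes <- graph_nodes(g)
  state <- as_state_tibble(state, nodes, params$m)
  hi <- match(g$to, nodes)
  ti <- match(g$from, nodes)
  contrib <- g$weight * edge_payoff(state$label[hi], state$k[hi],
                                    state$label[ti], state$k[ti], params)
  pay <- as.numeric(rowsum(c(contrib, rep(0, length(nodes))),
                           c(nodes[hi], nodes), reorder = FALSE)[nodes, 1])
  tibble(node = nodes, payoff = pay, fitness = exp(params$delta * pay))
}

#' Exponential fitness
#' @param payoff Total payoff (vectorized).
#' @param delta Selection strength.
#' @return `exp(delta * payoff)`.
#' @export
fitness <- function(payoff, delta) exp(delta * payoff)

state_to_cpp <- function(state) {
  list(label = as.integer(state$label == "C"), k = as.integer(state$k))
}

#' Run the birth-death Moran simulation
#'
#' Iterates the seeded Moran process for `steps` events, recording the full
#' population state at step 0 and every `sample_every` steps thereafter.
#' Reruns with the same seed and inputs are bit-identical.
#'
#' @param g An [ek_graph()] interaction graph.
#' @param params An [ek_params()].
#' @param steps Number of birth-death events (the study's standard long run is
#'   8e6; scaled-down runs of 8e5 retain hundreds of mutation periods).
#' @param seed Integer seed for the whole run (initial state + dynamics).
#' @param sample_every Sampling stride in steps (default 800).
#' @param burn_in Steps to discard from the record (default 0: step 0 is
#'   recorded; long runs amortize transients, so burn-in is opt-in).
#' @param reproduction Optional reproduction graph; defaults to
#'   [derive_reproduction_graph()] of `g`.
#' @param init Optional initial state tibble; defaults to a uniform random
#'   state drawn inside the seeded stream.
#' @return An `ek_sim` object: list with `metrics` (tibble `step`, `f_comm`,
#'   `rho`), sampled `labels`/`phases` matrices (samples x nodes), the final
#'   `payoff` vector, `n_mutations`, and the run configuration.
#' @examples
#' sim <- run_simulation(complete_graph(20), ek_params(), steps = 2e4, seed = 1)
#' glance(sim)
#' @export
run_simulation <- function(g, params = ek_params(), steps = 8e5, seed = 1L,
                           sample_every = 800L, burn_in = 0, reproduction = NULL,
                           init = NULL) {
  assert_ek_graph(g)
  stopifnot(steps >= 1, sample_every >= 1, burn_in >= 0, burn_in < steps)
  nodes <- graph_nodes(g)
  gr <- if (is.null(reproduction)) derive_reproduction_graph(g) else reproduction
  set.seed(seed)
  state0 <- if (is.null(init)) random_state(nodes, params$m)
            else as_state_tibble(init, nodes, params$m)
  ei <- edges_indexed(g)
  er <- edges_indexed(gr)
  s0 <- state_to_cpp(state0)
  res <- .run_moran_cpp(ei$tail, ei$head, ei$w, er$tail, er$head, er$w,
                        s0$label, s0$k, unclass(params),
                        as.double(steps), as.integer(sample_every))
  if (burn_in > 0) {
    keep <- res$step >= burn_in
    res$labels <- res$labels[keep, , drop = FALSE]
    res$phases <- res$phases[keep, , drop = FALSE]
    res$step <- res$step[keep]
  }
  phases_rad <- 2 * pi * res$phases / params$m
  metrics <- tibble(
    step = res$step,
    f_comm = rowMeans(res$labels),
    rho = Mod(rowMeans(exp(1i * phases_rad))))
  structure(list(
    metrics = metrics, labels = res$labels, phases = res$phases,
    payoff = res$payoff, n_mutations = res$n_mutations,
    graph = g, reproduction = gr, params = params,
    nodes = nodes, steps = steps, seed = seed, sample_every = sample_every,
    burn_in = burn_in),
    class = "ek_sim")
}

#' @export
print.ek_sim <- function(x, ...) {
  cat(sprintf(
    "# ek_sim: N=%d, %g steps (seed %s), %d samples, %g mutations\n",
    length(x$nodes), x$steps, format(x$seed), nrow(x$metrics), x$n_mutations))
  print(glance(x))
  invisible(x)
}

#' Extract the sampled state at one record
#' @param sim An `ek_sim`.
#' @param i Sample row index (1-based; 1 is step 0).
#' @return A state tibble.
#' @export
sim_state <- function(sim, i) {
  k <- as.integer(sim$phases[i, ])
  tibble(node = sim$nodes,
         label = ifelse(sim$labels[i, ] == 1, "C", "N"),
         k = k, phase = 2 * pi * k / sim$params$m)
}

#' @export
tidy.ek_sim <- function(x, ...) x$metrics

#' @export
glance.ek_sim <- function(x, ...) {
  fc <- x$metrics$f_comm
  tibble(
    n_samples = nrow(x$metrics),
    mean_f_comm = mean(fc),
    mean_rho = mean(x$metrics$rho),
    fraction_monomorphic = mean(fc == 0 | fc == 1),
    fraction_all_C = mean(fc == 1),
    fraction_all_N = mean(fc == 0),
    n_mutations = x$n_mutations)
}

#' @export
autoplot.ek_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("f_comm", "rho"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Run until the population is monomorphic
#'
#' Iterates the same Moran engine until every player shares one (label, phase)
#' state or `max_steps` is hit. Used for fixation-probability experiments
#' (e.g. a single mutant in a resident population).
#'
#' @inheritParams run_simulation
#' @param max_steps Step cap.
#' @return A list: `fixed` (logical), `steps`, and the final `label`
#'   (`"C"`/`"N"`) and phase index `k` of the (monomorphic) population.
#' @export
run_to_fixation <- function(g, params, init, max_steps = 1e7,
                            reproduction = NULL, seed = NULL) {
  assert_ek_graph(g)
  if (!is.null(seed)) set.seed(seed)
  nodes <- graph_nodes(g)
  gr <- if (is.null(reproduction)) derive_reproduction_graph(g) else reproduction
  state0 <- as_state_tibble(init, nodes, params$m)
  ei <- edges_indexed(g)
  er <- edges_indexed(gr)
  s0 <- state_to_cpp(state0)
  res <- .run_to_fixation_cpp(ei$tail, ei$head, ei$w, er$tail, er$head, er$w,
                              s0$label, s0$k, unclass(params),
                              as.double(max_steps))
  list(fixed = res$fixed, steps = res$steps,
       label = if (res$label == 1) "C" else "N", k = res$k)
}
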