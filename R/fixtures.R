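# Synthetic inputs: connectome-like random graphs matching a printed
# structural census, and hand-shaped community order-parameter traces for
# exercising the chimera/metastability indices.

#' Synthesize a connectome-like weighted directed graph
#'
#' Draws a random directed integer-weighted graph whose structural census
#' exactly matches the target counts (defaults: the 300-node *C. elegans*
#' chemical-connectome census of 38 self-loops, 669 bidirectional edge pairs,
#' 2,331 unpaired edges and 5 dangling nodes; 38 + 2*669 + 2331 = 3,707
#' directed edges). Dangling nodes are designated up front and receive no
#' out-edges — a fixture construction, not biology. Weights are i.i.d.
#' `1 + Geometric` (mean `weight_mean`); the real connectome's weight
#' distribution is not claimed to be matched.
#'
#' @param n_nodes,n_self_loops,n_bidirectional_pairs,n_unpaired,n_dangling
#'   Target census counts.
#' @param weight_mean Mean of the integer weight law (>= 1).
#' @param seed Integer seed.
#' @return An [ek_graph()] whose [graph_census()] equals the targets.
#' @export
synth_connectome <- function(n_nodes = 300L, n_self_loops = 38L,
                             n_bidirectional_pairs = 669L,
                             n_unpaired = 2331L, n_dangling = 5L,
                             weight_mean = 3, seed = 1L) {
  stopifnot(weight_mean >= 1)
  n_nodes <- as.integer(n_nodes)
  n_src <- n_nodes - n_dangling
  if (n_src < 2) abort("too many dangling nodes for the node count.")
  if (n_self_loops > n_src) abort("more self-loops than non-dangling nodes.")
  if (n_bidirectional_pairs > choose(n_src, 2)) {
    abort("more bidirectional pairs than available node pairs.")
  }
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n_nodes) - 1L)
  dangling <- sample(ids, n_dangling)
  src_pool <- setdiff(ids, dangling)

  loops <- sample(src_pool, n_self_loops)

  # reciprocal pairs: both endpoints need out-edges, so draw from src_pool
  pair_keys <- character(0)
  from <- character(0)
  to <- character(0)
  while (length(pair_keys) < n_bidirectional_pairs) {
    need <- n_bidirectional_pairs - length(pair_keys)
    u <- sample(src_pool, 2 * need, replace = TRUE)
    v <- sample(src_pool, 2 * need, replace = TRUE)
    ok <- u != v
    u <- u[ok]; v <- v[ok]
    key <- ifelse(u < v, paste(u, v), paste(v, u))
    keep <- !duplicated(key) & !key %in% pair_keys
    u <- u[keep][seq_len(min(need, sum(keep)))]
    v <- v[keep][seq_len(min(need, sum(keep)))]
    pair_keys <- c(pair_keys, ifelse(u < v, paste(u, v), paste(v, u)))
    from <- c(from, u, v)
    to <- c(to, v, u)
  }

  # unpaired edges: source must be non-dangling; target anywhere; neither
  # direction may already exist (that would create an extra reciprocal pair).
  # A hash set over "u|v" keys blocks both directions of every placed edge.
  used <- new.env(hash = TRUE, size = 4L * (n_unpaired + n_bidirectional_pairs))
  block <- function(u, v) {
    assign(paste0(u, "|", v), TRUE, envir = used)
    assign(paste0(v, "|", u), TRUE, envir = used)
  }
  free <- function(u, v) {
    !exists(paste0(u, "|", v), envir = used, inherits = FALSE)
  }
  for (i in seq_along(from)) block(from[i], to[i])
  uf <- character(n_unpaired)
  ut <- character(n_unpaired)
  placed <- 0L
  while (placed < n_unpaired) {
    u <- sample(src_pool, 1L)
    v <- sample(ids, 1L)
    if (u == v || !free(u, v)) next
    placed <- placed + 1L
    uf[placed] <- u
    ut[placed] <- v
    block(u, v)
  }

  # repair: every non-dangling node needs out-degree >= 1; re-source unpaired
  # edges from multi-edge sources onto starved nodes (census preserved)
  repeat {
    out_deg <- table(factor(c(from, uf, loops), levels = ids))
    starved <- setdiff(names(out_deg)[out_deg == 0], dangling)
    if (length(starved) == 0) break
    for (s in starved) {
      src_counts <- table(uf)
      i <- which(src_counts[uf] > 1)[1]
      repeat {
        v <- sample(ids, 1L)
        if (v != s && free(s, v)) break
      }
      block(s, v)
      uf[i] <- s
      ut[i] <- v
    }
  }

  edges <- tibble(
    from = c(loops, from, uf),
    to = c(loops, to, ut))
  p <- 1 / weight_mean
  edges$weight <- 1L + stats::rgeom(nrow(edges), p)
  ek_graph(edges, nodes = ids)
}

#' Synthetic community order-parameter traces
#'
#' Builds a `T x M` matrix of per-community `rho_m` traces from simple
#' patterns, for exercising [chimera_index()] and [metastability_index()].
#' Patterns per community: `list(type = "constant", value = v)`,
#' `list(type = "alternating", v1 = , v2 = )` (strict 0/1-style square wave),
#' or `list(type = "noisy", mean = , sd = )` (Gaussian, clipped to `[0, 1]`).
#'
#' @param patterns A list of pattern specs, one per community.
#' @param T_steps Number of sampled steps (rows).
#' @param seed Integer seed (used by `"noisy"` patterns).
#' @return A numeric `T_steps x M` matrix.
#' @export
synth_rho_traces <- function(patterns, T_steps, seed = 1L) {
  set.seed(seed)
  cols <- lapply(patterns, function(sp) {
    switch(sp$type,
      constant = rep(sp$value, T_steps),
      alternating = rep_len(c(sp$v1, sp$v2), T_steps),
      noisy = pmin(1, pmax(0, stats::rnorm(T_steps, sp$mean, sp$sd))),
      abort(sprintf("unknown trace pattern type '%s'", sp$type)))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("rho_", seq_along(patterns))
  out
}
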