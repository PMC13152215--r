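#' Weighted directed interaction graphs
#'
#' An `ek_graph` is a tibble of directed edges (`from`, `to`, `weight`) plus a
#' `nodes` attribute holding every node label in first-appearance order. The
#' interaction graph says *from whom* a player receives payoffs: the edge
#' `u -> v` delivers a payoff to the head `v`, scaled by the integer weight
#' which counts the number of games played along that connection. A companion
#' reproduction graph (same edges, plus a self-loop on every originally
#' dangling node) says *to whom* a strategy can spread.
#'
#' @param edges A data frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Duplicate `(from, to)` rows are merged by summing weights,
#'   with a warning.
#' @param nodes Optional character vector of node labels; defaults to the
#'   labels in `edges` in first-appearance order (from before to, row order).
#'   Extra labels add isolated nodes.
#' @param directed Logical flag, kept for round-tripping file metadata.
#'   Undirected inputs are expanded to reciprocal directed edges on load.
#' @return An `ek_graph`: a tibble of edges with attributes `nodes` and
#'   `directed`.
#' @examples
#' g <- ek_graph(data.frame(from = c("a", "b"), to = c("b", "a"), weight = c(2, 1)))
#' graph_census(g)
#' @export
ek_graph <- function(edges, nodes = NULL, directed = TRUE) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1L
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  w <- edges$weight
  if (any(!is.finite(w)) || any(w != as.integer(w)) || any(w < 1)) {
    abort("edge weights must be positive integers (weights count games).")
  }
  edges$weight <- as.integer(w)
  if (anyDuplicated(edges[c("from", "to")])) {
    ndup <- sum(duplicated(edges[c("from", "to")]))
    warn(sprintf("merged %d duplicate (from, to) edge row(s) by summing weights", ndup))
    edges <- edges %>%
      group_by(.data$from, .data$to) %>%
      summarise(weight = sum(.data$weight), .groups = "drop")
  }
  seen <- unique(as.vector(rbind(edges$from, edges$to)))
  nodes <- if (is.null(nodes)) seen else unique(c(as.character(nodes), seen))
  if (length(nodes) < 2) {
    abort("a graph needs at least 2 nodes.")
  }
  edges <- edges[order(match(edges$from, nodes), match(edges$to, nodes)), ]
  new_ek_graph(edges, nodes, directed)
}

new_ek_graph <- function(edges, nodes, directed = TRUE) {
  edges <- as_tibble(edges)[c("from", "to", "weight")]
  structure(edges,
    nodes = nodes, directed = isTRUE(directed),
    class = c("ek_graph", class(tibble())))
}

#' @export
print.ek_graph <- function(x, ...) {
  cat(sprintf(
    "# ek_graph: %d nodes, %d directed edges, total weight %d\n",
    length(graph_nodes(x)), nrow(x), sum(x$weight)))
  NextMethod()
}

#' Node labels of an `ek_graph`
#' @param g An `ek_graph`.
#' @return Character vector of node labels in index order.
#' @export
graph_nodes <- function(g) attr(g, "nodes")

assert_ek_graph <- function(g) {
  if (!inherits(g, "ek_graph")) abort("expected an `ek_graph` (see `ek_graph()`).")
  invisible(g)
}

#' Read an edge list from a delimited text file
#'
#' Expects a header `source<sep>target[<sep>weight]`; tab-separated by default
#' with comma autodetected from the header line. A missing weight column
#' defaults to 1. Duplicate rows are merged by weight summation (warning).
#'
#' @param path File path.
#' @param directed Logical; undirected files get both edge directions
#'   (reciprocal weights equal).
#' @return An [ek_graph()].
#' @export
load_edge_list <- function(path, directed = TRUE) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort("empty edge-list file (no header).")
  sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
    colClasses = "character", strip.white = TRUE, quote = "",
    blank.lines.skip = TRUE)
  if (ncol(df) < 2) abort("edge list needs at least `source` and `target` columns.")
  names(df)[1:2] <- c("from", "to")
  if (ncol(df) >= 3) names(df)[3] <- "weight"
  if (any(df$from == "" | df$to == "")) {
    bad <- which(df$from == "" | df$to == "")[1]
    abort(sprintf("malformed edge row at data line %d of %s", bad, path))
  }
  if ("weight" %in% names(df)) {
    wnum <- suppressWarnings(as.numeric(df$weight))
    if (anyNA(wnum)) {
      bad <- which(is.na(wnum))[1]
      abort(sprintf("non-numeric weight at data line %d of %s", bad, path))
    }
    if (any(wnum != round(wnum)) || any(wnum < 1)) {
      bad <- which(wnum != round(wnum) | wnum < 1)[1]
      abort(sprintf("non-positive or non-integer weight at data line %d of %s", bad, path))
    }
    df$weight <- as.integer(round(wnum))
  }
  if (!directed) {
    rev <- df[df$from != df$to, , drop = FALSE]
    names(rev)[names(rev) == "from"] <- ".tmp"
    names(rev)[names(rev) == "to"] <- "from"
    names(rev)[names(rev) == ".tmp"] <- "to"
    df <- rbind(df, rev[names(df)])
  }
  ek_graph(df, directed = TRUE)
}

#' Write an `ek_graph` as a TSV edge list
#' @param g An `ek_graph`.
#' @param path Output path; header `source\ttarget\tweight`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  assert_ek_graph(g)
  df <- data.frame(source = g$from, target = g$to, weight = g$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert to / from igraph
#'
#' Weights travel as the numeric edge attribute `weight`; GraphML i/o is
#' delegated to igraph.
#' @param g An `ek_graph`.
#' @return `as_igraph()` returns an igraph object; `load_graphml()` an
#'   [ek_graph()].
#' @export
as_igraph <- function(g) {
  assert_ek_graph(g)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$from, to = g$to, weight = as.numeric(g$weight)),
    directed = TRUE, vertices = data.frame(name = graph_nodes(g)))
  ig
}

#' @rdname as_igraph
#' @param path GraphML file path.
#' @export
load_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  df <- igraph::as_data_frame(ig, what = "edges")
  w <- if ("weight" %in% names(df)) as.integer(round(df$weight)) else 1L
  ek_graph(tibble(from = df$from, to = df$to, weight = w),
           nodes = igraph::V(ig)$name)
}

#' @rdname as_igraph
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Complete (well-mixed) interaction graph
#'
#' Every ordered pair of distinct players is connected with weight 1 — the
#' well-mixed population of the model. No self-loops, so the reproduction
#' graph is identical.
#'
#' @param N Number of players (>= 2).
#' @return An [ek_graph()] with `N (N - 1)` edges.
#' @export
complete_graph <- function(N) {
  if (!is.numeric(N) || N < 2 || N != round(N)) abort("`N` must be an integer >= 2.")
  N <- as.integer(N)
  ids <- as.character(seq_len(N) - 1L)
  from <- rep(ids, each = N)
  to <- rep(ids, times = N)
  keep <- from != to
  new_ek_graph(tibble(from = from[keep], to = to[keep], weight = 1L), ids)
}

#' Derive the reproduction graph
#'
#' Copies the interaction graph and adds one weight-1 self-loop to every
#' dangling node (out-degree 0) so the birth-death step is always well
#' defined: a dangling node selected for birth replaces itself (a no-op except
#' under mutation).
#'
#' @param g An [ek_graph()] interaction graph.
#' @return An `ek_graph` with minimum out-degree 1.
#' @export
derive_reproduction_graph <- function(g) {
  assert_ek_graph(g)
  nodes <- graph_nodes(g)
  dangling <- setdiff(nodes, unique(g$from))
  if (length(dangling) == 0) return(g)
  new_ek_graph(
    bind_rows(as_tibble(g), tibble(from = dangling, to = dangling, weight = 1L)),
    nodes)
}

#' Drop edge weights
#'
#' Sets every weight to 1 while keeping the topology — the "unweighted,
#' directed" variant used to separate the influence of weights from that of
#' direction.
#' @param g An [ek_graph()].
#' @return An `ek_graph` with unit weights.
#' @export
strip_weights <- function(g) {
  assert_ek_graph(g)
  out <- as_tibble(g)
  out$weight <- 1L
  new_ek_graph(out, graph_nodes(g), attr(g, "directed"))
}

#' Symmetrize a directed graph
#'
#' Builds the "weighted, undirected" variant: for every unordered pair with
#' any edge, both directions are kept with the combined weight (reciprocal
#' weights summed by default, preserving the total count of games; `max` and
#' `mean` are available). Self-loop weights are left unchanged. Note that an
#' already-symmetric pair with equal weights `w` therefore ends up at `2 w`
#' under `combine = "sum"`.
#'
#' @param g An [ek_graph()].
#' @param combine One of `"sum"`, `"max"`, `"mean"` for reciprocal weights.
#' @return A symmetric `ek_graph`.
#' @export
symmetrize <- function(g, combine = c("sum", "max", "mean")) {
  assert_ek_graph(g)
  combine <- match.arg(combine)
  f <- switch(combine, sum = sum, max = max,
              mean = function(w) as.integer(max(1, round(mean(w)))))
  loops <- g[g$from == g$to, , drop = FALSE]
  rest <- g[g$from != g$to, , drop = FALSE]
  if (nrow(rest) > 0) {
    key <- ifelse(rest$from < rest$to,
                  paste(rest$from, rest$to, sep = "\r"),
                  paste(rest$to, rest$from, sep = "\r"))
    wk <- vapply(split(rest$weight, key), function(w) as.integer(f(w)), integer(1))
    parts <- strsplit(names(wk), "\r", fixed = TRUE)
    u <- vapply(parts, `[`, "", 1L)
    v <- vapply(parts, `[`, "", 2L)
    sym <- tibble(from = c(u, v), to = c(v, u), weight = rep(unname(wk), 2L))
  } else {
    sym <- tibble(from = character(), to = character(), weight = integer())
  }
  out <- bind_rows(as_tibble(loops), sym)
  nodes <- graph_nodes(g)
  out <- out[order(match(out$from, nodes), match(out$to, nodes)), ]
  new_ek_graph(out, nodes, attr(g, "directed"))
}

#' Census of a directed graph
#'
#' Counts the structural features used to describe the *C. elegans* chemical
#' connectome: self-loops, bidirectional (reciprocal) edge pairs, unpaired
#' directed edges, dangling nodes (out-degree 0) and total weight. The
#' identity `2 * pairs + unpaired + self_loops = edges` always holds.
#'
#' @param g An [ek_graph()].
#' @return A one-row tibble with columns `n_nodes`, `n_edges`, `n_self_loops`,
#'   `n_bidirectional_pairs`, `n_unpaired_edges`, `n_dangling`, `total_weight`.
#' @export
graph_census <- function(g) {
  assert_ek_graph(g)
  nodes <- graph_nodes(g)
  loops <- g$from == g$to
  nonloop <- g[!loops, , drop = FALSE]
  fwd <- paste(nonloop$from, nonloop$to, sep = "\r")
  rev <- paste(nonloop$to, nonloop$from, sep = "\r")
  paired <- fwd %in% rev
  tibble(
    n_nodes = length(nodes),
    n_edges = nrow(g),
    n_self_loops = sum(loops),
    n_bidirectional_pairs = sum(paired) %/% 2L,
    n_unpaired_edges = sum(!paired),
    n_dangling = sum(!nodes %in% unique(g$from)),
    total_weight = sum(g$weight))
}

#' @export
tidy.ek_graph <- function(x, ...) as_tibble(x)

#' @export
glance.ek_graph <- function(x, ...) graph_census(x)
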