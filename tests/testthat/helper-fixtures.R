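# Shared fixtures built in code.

toy_graph <- function() {
  ek_graph(data.frame(from = c("a", "b", "a"),
                      to = c("b", "a", "a"),
                      weight = c(2L, 1L, 5L)))
}

# random small weighted directed graph (may contain self-loops)
random_graph <- function(N, n_edges, seed) {
  set.seed(seed)
  ids <- as.character(seq_len(N) - 1L)
  from <- sample(ids, n_edges, replace = TRUE)
  to <- sample(ids, n_edges, replace = TRUE)
  w <- sample(1:5, n_edges, replace = TRUE)
  df <- stats::aggregate(w, list(from = from, to = to), sum)
  ek_graph(data.frame(from = df$from, to = df$to, weight = df$x), nodes = ids)
}

monomorphic_state <- function(nodes, label, k, m = 20L) {
  tibble::tibble(node = nodes, label = label, k = as.integer(k),
                 phase = 2 * pi * k / m)
}

# state with one mutant at node 1, residents elsewhere
single_mutant_state <- function(nodes, res, mut, m = 20L) {
  st <- monomorphic_state(nodes, res$label, res$k, m)
  st$label[1] <- mut$label
  st$k[1] <- as.integer(mut$k)
  st$phase[1] <- 2 * pi * mut$k / m
  st
}

# Independent fixation-probability oracle: exact absorbing Markov chain over
# the number of mutants j = 0..N on a complete graph (no self-loops), one
# birth-death event per step, exponential fitness on total payoff.
fixation_chain_oracle <- function(resident, mutant, N, params) {
  a_MM <- edge_payoff(mutant$label, mutant$k, mutant$label, mutant$k, params)
  a_MR <- edge_payoff(mutant$label, mutant$k, resident$label, resident$k, params)
  a_RM <- edge_payoff(resident$label, resident$k, mutant$label, mutant$k, params)
  a_RR <- edge_payoff(resident$label, resident$k, resident$label, resident$k, params)
  up <- numeric(N + 1)
  down <- numeric(N + 1)
  for (j in 1:(N - 1)) {
    pi_mut <- (j - 1) * a_MM + (N - j) * a_MR
    pi_res <- j * a_RM + (N - j - 1) * a_RR
    fm <- exp(params$delta * pi_mut)
    fr <- exp(params$delta * pi_res)
    tot <- j * fm + (N - j) * fr
    up[j + 1] <- (j * fm / tot) * (N - j) / (N - 1)
    down[j + 1] <- ((N - j) * fr / tot) * j / (N - 1)
  }
  # solve h_j = P(absorb at N | start j) by the linear system
  A <- matrix(0, N - 1, N - 1)
  b <- numeric(N - 1)
  for (j in 1:(N - 1)) {
    stay <- 1 - up[j + 1] - down[j + 1]
    A[j, j] <- 1 - stay
    if (j > 1) A[j, j - 1] <- -down[j + 1]
    if (j < N - 1) A[j, j + 1] <- -up[j + 1]
    if (j == N - 1) b[j] <- up[j + 1]
  }
  solve(A, b)[1]
}

# two-pass brute-force variance oracles for the chimera/metastability indices
chi_oracle <- function(x) {
  M <- ncol(x)
  s <- 0
  for (t in seq_len(nrow(x))) {
    mu <- sum(x[t, ]) / M
    s <- s + sum((x[t, ] - mu)^2) / (M - 1)
  }
  s / nrow(x)
}

lambda_oracle <- function(x) {
  T_ <- nrow(x)
  s <- 0
  for (m in seq_len(ncol(x))) {
    mu <- sum(x[, m]) / T_
    s <- s + sum((x[, m] - mu)^2) / (T_ - 1)
  }
  s / ncol(x)
}
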