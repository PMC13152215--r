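test_that("communicative fraction counts labels only", {
  st <- random_state(20, m = 20L, seed = 1)
  st$label <- rep(c("C", "N"), c(5, 15))
  expect_equal(communicative_fraction(st), 0.25)
  st$k <- sample(st$k)  # phases are irrelevant
  expect_equal(communicative_fraction(st), 0.25)
  st$label <- "C"
  expect_equal(communicative_fraction(st), 1)
  st$label <- "N"
  expect_equal(communicative_fraction(st), 0)
})

test_that("order parameter measures phase coherence", {
  m <- 20L
  aligned <- monomorphic_state(as.character(1:10), "C", 7, m)
  expect_equal(order_parameter(aligned), 1)
  spread <- tibble::tibble(node = as.character(1:20), label = "C",
                           k = 0:19, phase = 2 * pi * (0:19) / m)
  expect_equal(order_parameter(spread), 0, tolerance = 1e-12)
  halves <- tibble::tibble(node = as.character(1:10), label = "C",
                           k = rep(c(0L, 10L), 5),
                           phase = rep(c(0, pi), 5))
  expect_equal(order_parameter(halves), 0, tolerance = 1e-12)
})

test_that("community order parameters reduce, saturate and cancel as expected", {
  m <- 20L
  st <- random_state(9, m, seed = 2)
  whole <- tibble::tibble(node = st$node, community = 1L)
  expect_equal(community_order(st, whole)$rho_m, order_parameter(st))
  singles <- tibble::tibble(node = st$node, community = seq_len(9))
  expect_equal(community_order(st, singles)$rho_m, rep(1, 9))
  anti <- tibble::tibble(node = c("a", "b"), label = "C", k = c(0L, 10L),
                         phase = c(0, pi))
  expect_equal(
    community_order(anti, tibble::tibble(node = c("a", "b"), community = 1L))$rho_m,
    0, tolerance = 1e-12)
  expect_error(community_order(st, singles[-1, ]), "community")
})

test_that("chimera and metastability indices match their defining traces", {
  # three coherent + three disordered communities, forever: the maximum
  chi_max <- chimera_index(synth_rho_traces(
    c(replicate(3, list(type = "constant", value = 1), simplify = FALSE),
      replicate(3, list(type = "constant", value = 0), simplify = FALSE)),
    T_steps = 50))
  expect_equal(chi_max, 0.3, tolerance = 1e-12)
  # M = 2 version of the same bound: M / (4 (M - 1)) = 0.5
  expect_equal(chimera_index(cbind(rep(1, 10), rep(0, 10))), 0.5)
  # homogeneous communities: zero chimera; constant traces: zero metastability
  flat <- synth_rho_traces(
    replicate(4, list(type = "constant", value = 0.6), simplify = FALSE), 30)
  expect_equal(chimera_index(flat), 0)
  expect_equal(metastability_index(flat), 0)
  # equal occupancy of 0 and 1: sample variance -> 1/4 at large T
  alt <- synth_rho_traces(
    replicate(6, list(type = "alternating", v1 = 0, v2 = 1), simplify = FALSE),
    1e4)
  expect_lt(abs(metastability_index(alt) - 0.25), 1e-4)
  # small-T sample-variance behaviour: T = 2 trace (0, 1) gives 1/2
  expect_equal(metastability_index(matrix(c(0, 1), 2, 1)), 0.5)
  expect_error(chimera_index(matrix(1, 5, 1)), "M >= 2")
  expect_error(metastability_index(matrix(1, 1, 3)), "T >= 2")
})

test_that("indices agree with two-pass brute-force variance oracles", {
  for (seed in 1:5) {
    x <- synth_rho_traces(
      replicate(6, list(type = "noisy", mean = runif(1), sd = 0.2),
                simplify = FALSE), 100, seed = seed)
    expect_equal(chimera_index(x), chi_oracle(x), tolerance = 1e-12)
    expect_equal(metastability_index(x), lambda_oracle(x), tolerance = 1e-12)
    cs <- chimera_summary(x)
    expect_equal(cs$chi, chi_oracle(x))
    expect_equal(cs$lambda, lambda_oracle(x))
    # theoretical bounds
    M <- ncol(x); T_ <- nrow(x)
    expect_lte(cs$chi, M / (4 * (M - 1)) + 1e-12)
    expect_lte(cs$lambda, T_ / (4 * (T_ - 1)) + 1e-12)
  }
})

test_that("game censuses conserve weight and find the expected plurality", {
  p <- ek_params()
  g <- complete_graph(4)
  all_c <- monomorphic_state(graph_nodes(g), "C", 3)
  cen <- game_census(g, all_c, p)
  expect_equal(sum(cen$fraction), 1)
  expect_equal(cen$game, "cooperation")
  expect_equal(plurality_game(cen, all_c), "all-C")
  expect_equal(plurality_mixed_game(cen, all_c), "all-C")
  all_n <- monomorphic_state(graph_nodes(g), "N", 0)
  expect_equal(plurality_game(game_census(g, all_n, p), all_n), "all-N")
  # one C, one N at equal phase: the single mixed edge pair is a chicken game
  g2 <- complete_graph(2)
  st2 <- monomorphic_state(graph_nodes(g2), "C", 0)
  st2$label <- c("C", "N")
  cen2 <- game_census(g2, st2, p)
  expect_equal(cen2$game, "chicken")
  expect_equal(cen2$fraction, 1)
  expect_equal(plurality_game(cen2, st2), "chicken")
  expect_equal(plurality_mixed_game(cen2, st2), "chicken")
  # weighted plurality and the alphabetical tie rule
  expect_equal(plurality_from_weights(c("chicken", "dilemma"), c(5, 3)), "chicken")
  expect_equal(plurality_from_weights(c("dilemma", "chicken"), c(4, 4)), "chicken")
})

test_that("mixed population with no mixed edges reports none", {
  p <- ek_params()
  # two disconnected reciprocal pairs: C-C and N-N edges only
  g <- ek_graph(data.frame(from = c("a", "b", "c", "d"),
                           to = c("b", "a", "d", "c")))
  st <- tibble::tibble(node = c("a", "b", "c", "d"),
                       label = c("C", "C", "N", "N"),
                       k = 0L, phase = 0)
  cen <- game_census(g, st, p)
  expect_equal(plurality_mixed_game(cen, st), "none")
  expect_setequal(cen$game, c("cooperation", "neutral"))
})

test_that("community detection separates disconnected cliques and round-trips files", {
  clique <- function(ids) {
    df <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    df[df$from != df$to, ]
  }
  g <- ek_graph(rbind(clique(c("a", "b", "c")), clique(c("x", "y", "z"))))
  comm <- suppressMessages(detect_communities(g, seed = 1))
  expect_equal(length(unique(comm$community)), 2)
  expect_equal(length(unique(comm$community[comm$node %in% c("a", "b", "c")])), 1)
  expect_equal(length(unique(comm$community[comm$node %in% c("x", "y", "z")])), 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_communities(comm, path)
  expect_equal(load_communities(path), comm)
})

test_that("per-run series and game metrics have consistent shapes", {
  g <- complete_graph(6)
  p <- ek_params(m = 8L, mu = 0.01)
  sim <- run_simulation(g, p, steps = 4000, seed = 12, sample_every = 400)
  comm <- tibble::tibble(node = graph_nodes(g), community = rep(1:2, each = 3))
  ser <- community_order_series(sim, comm)
  expect_equal(names(ser), c("step", "rho_1", "rho_2"))
  expect_equal(nrow(ser), nrow(sim$metrics))
  expect_true(all(ser$rho_1 >= 0 & ser$rho_1 <= 1))
  gm <- sim_game_metrics(sim)
  expect_equal(nrow(gm), nrow(sim$metrics))
  known <- c(game_type_names(), "all-C", "all-N", "none")
  expect_true(all(gm$plurality_game %in% known))
  expect_true(all(gm$plurality_mixed_game %in% known))
  # per-sample labels agree with a direct census of the sampled state
  i <- nrow(sim$metrics)
  st <- sim_state(sim, i)
  expect_equal(gm$plurality_game[i], plurality_game(game_census(g, st, p), st))
})
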