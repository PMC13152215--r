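# Rare-mutation analytics for the well-mixed (complete-graph) population.
#
# With mu << 1 a mutant lineage fixates or dies out before the next mutation
# arrives, so the population hops between the 2m monomorphic states. The
# long-run communicative fraction is then the C-probability mass of the
# stationary distribution of the embedded Markov chain whose A -> B rate is
# proportional to the fixation probability of a single B mutant in an A
# resident population (mutation targets drawn uniformly over all 2m states).

all_strategies <- function(m) {
  tibble(label = rep(c("C", "N"), each = m), k = rep(seq_len(m) - 1L, 2))
}

#' Fixation probability of a single mutant (complete graph)
#'
#' Standard birth-death fixation probability under exponential fitness,
#' `rho = 1 / (1 + sum_{k=1}^{N-1} prod_{j=1}^{k} gamma_j)` with
#' `gamma_j = exp(delta * (pi_res(j) - pi_mut(j)))`. With `j` mutants on a
#' complete graph (one in-edge per ordered pair, no self-interaction) the
#' total payoffs are `pi_mut(j) = (j-1) a_MM + (N-j) a_MR` and
#' `pi_res(j) = j a_RM + (N-j-1) a_RR`, where `a_XY` is the per-game
#' [edge_payoff()] of an X player receiving from a Y player.
#'
#' @param resident,mutant Lists or one-row data frames with `label` and `k`.
#' @param N Population size (>= 2).
#' @param params An [ek_params()].
#' @return The fixation probability; exactly `1/N` at `delta = 0`.
#' @export
pairwise_fixation <- function(resident, mutant, N, params) {
  if (!is.numeric(N) || N < 2 || N != round(N)) abort("`N` must be an integer >= 2.")
  a_MM <- edge_payoff(mutant$label, mutant$k, mutant$label, mutant$k, params)
  a_MR <- edge_payoff(mutant$label, mutant$k, resident$label, resident$k, params)
  a_RM <- edge_payoff(resident$label, resident$k, mutant$label, mutant$k, params)
  a_RR <- edge_payoff(resident$label, resident$k, resident$label, resident$k, params)
  j <- seq_len(N - 1)
  pi_mut <- (j - 1) * a_MM + (N - j) * a_MR
  pi_res <- j * a_RM + (N - j - 1) * a_RR
  log_gamma <- params$delta * (pi_res - pi_mut)
  1 / (1 + sum(exp(cumsum(log_gamma))))
}

#' Table of pairwise fixation probabilities over all monomorphic states
#'
#' @param N Population size.
#' @param params An [ek_params()].
#' @return A `2m x 2m` matrix; entry `(A, B)` is the fixation probability of
#'   one B mutant in an A resident population. Diagonal entries are set to 0
#'   (a same-state "mutant" changes nothing).
#' @export
fixation_table <- function(N, params) {
  states <- all_strategies(params$m)
  n <- nrow(states)
  tab <- matrix(0, n, n)
  ids <- paste0(states$label, states$k)
  dimnames(tab) <- list(ids, ids)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      tab[a, b] <- pairwise_fixation(states[a, ], states[b, ], N, params)
    }
  }
  tab
}

#' Analytic stationary communicative fraction (well-mixed, rare mutation)
#'
#' Builds the embedded Markov chain over the `2m` monomorphic states with
#' transition rate `(A -> B)` proportional to `pairwise_fixation(A, B) / 2m`,
#' solves for its stationary distribution, and sums the probability of
#' C-labelled states.
#'
#' @param N Population size.
#' @param params An [ek_params()].
#' @param detail If `TRUE`, also return the stationary distribution.
#' @return The stationary `f_comm` in `[0, 1]` (or a list when `detail`).
#' @export
stationary_fcomm <- function(N, params, detail = FALSE) {
  states <- all_strategies(params$m)
  tab <- fixation_table(N, params)
  n <- nrow(tab)
  Q <- tab / n            # uniform mutation kernel over the 2m targets
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # left null vector of Q, normalized: replace one balance equation by sum = 1
  A <- rbind(t(Q)[-1, , drop = FALSE], rep(1, n))
  pi_st <- solve(A, c(rep(0, n - 1), 1))
  if (any(pi_st < -1e-10)) abort("stationary solve produced negative mass; chain may be reducible.")
  pi_st <- pmax(pi_st, 0)
  pi_st <- pi_st / sum(pi_st)
  fc <- sum(pi_st[states$label == "C"])
  if (detail) list(f_comm = fc, stationary = tibble(states, p = pi_st)) else fc
}

#' Analytic f_comm curve over a B0 grid
#'
#' Varies the maximum joint benefit `B0`, rescaling `beta0` to keep
#' `beta0/B0` fixed (the study's convention).
#'
#' @param B0 Vector of joint-benefit values.
#' @param N Population size.
#' @param params Baseline [ek_params()] (supplies `beta0/B0`, `c`, `alpha`,
#'   `delta`, `m`).
#' @return A tibble `(B0, alpha, f_comm)` of class `ek_theory_curve`.
#' @export
theory_curve <- function(B0, N = 20, params = ek_params()) {
  ratio <- params$beta0 / params$B0
  fc <- vapply(B0, function(b) {
    stationary_fcomm(N, ek_params(B0 = b, beta0 = ratio * b, c = params$c,
                                  alpha = params$alpha, delta = params$delta,
                                  mu = params$mu, m = params$m))
  }, numeric(1))
  out <- tibble(B0 = B0, alpha = params$alpha, f_comm = fc)
  class(out) <- c("ek_theory_curve", class(out))
  out
}

#' @export
autoplot.ek_theory_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$B0, y = .data$f_comm,
                                       colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "maximum joint benefit B0", y = "f_comm",
                  colour = "alpha") +
    ggplot2::theme_minimal()
}

#' Break-even joint benefit
#'
#' The `B0` at which the analytic stationary communicative fraction crosses
#' one half, found by bisection on `[c/2, 4c]` (with `beta0/B0` held fixed).
#' The sigmoid shape is checked via the bracket endpoints.
#'
#' @param N Population size.
#' @param params An [ek_params()].
#' @param tol Bisection tolerance on `B0`.
#' @return The break-even `B0` (around `2.1 c` for `N = 20`, `alpha = 0.5`).
#' @export
break_even_B0 <- function(N = 20, params = ek_params(), tol = 1e-4) {
  ratio <- params$beta0 / params$B0
  fc_at <- function(b) {
    stationary_fcomm(N, ek_params(B0 = b, beta0 = ratio * b, c = params$c,
                                  alpha = params$alpha, delta = params$delta,
                                  mu = params$mu, m = params$m)) - 0.5
  }
  lo <- params$c / 2
  hi <- 4 * params$c
  flo <- fc_at(lo)
  fhi <- fc_at(hi)
  if (flo * fhi > 0) {
    abort(sprintf(
      "no sign change of f_comm - 1/2 on [%g, %g] (f_comm = %.4f / %.4f)",
      lo, hi, flo + 0.5, fhi + 0.5))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (flo * fc_at(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Closed-form break-even condition
#'
#' The symmetric-case reference `B0 = 2 (N - 1) c / (N - 2)`, about `0.21`
#' for `N = 20`, `c = 0.1`, with limit `2 c` as `N` grows.
#'
#' @param N Population size (>= 3).
#' @param c Communication cost.
#' @return The closed-form break-even `B0`.
#' @export
closed_form_break_even <- function(N, c = 0.1) {
  if (!is.numeric(N) || N < 3 || N != round(N)) abort("`N` must be an integer >= 3.")
  2 * (N - 1) * c / (N - 2)
}
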