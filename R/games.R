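#' Game and dynamics parameters
#'
#' Bundles the payoff and evolutionary parameters of the model. The defaults
#' are the study's standard operating point: cost `c = 0.1`, maximum joint
#' benefit `B0 = 1.5 c`, maximum mixed benefit `beta0 = 0.95 B0`, asymmetry
#' `alpha = 0.5` (symmetric), selection strength `delta = 0.2`, mutation rate
#' `mu = 1e-4`, and `m = 20` discrete phases. The dynamics depend only on the
#' combinations `B0/c`, `beta0/B0`, `alpha` and `delta * c` (besides `mu`, `m`).
#'
#' @param B0 Maximum joint benefit when both players communicate (> 0).
#' @param beta0 Maximum mixed benefit when exactly one player communicates.
#' @param c Communication cost paid by every communicative player (> 0).
#' @param alpha Benefit asymmetry in `[0, 1]`: the communicator's mixed
#'   benefit is scaled by `2 alpha`, the non-communicator's by `2 (1 - alpha)`;
#'   `alpha = 0.5` recovers the symmetric model.
#' @param delta Selection strength (>= 0); fitness is `exp(delta * payoff)`.
#' @param mu Mutation probability per birth-death event.
#' @param m Number of discrete phases `2 pi k / m`, `k = 0, ..., m - 1`.
#' @return A list of class `ek_params`.
#' @examples
#' p <- ek_params(alpha = 0.75)
#' edge_payoff("C", 0, "C", 0, p)   # B0 - c
#' @export
ek_params <- function(B0 = 0.15, beta0 = 0.95 * B0, c = 0.1, alpha = 0.5,
                      delta = 0.2, mu = 1e-4, m = 20L) {
  stopifnot(B0 > 0, beta0 > 0, c > 0, alpha >= 0, alpha <= 1,
            delta >= 0, mu >= 0, mu <= 1, m >= 2, m == round(m))
  structure(list(B0 = B0, beta0 = beta0, c = c, alpha = alpha,
                 delta = delta, mu = mu, m = as.integer(m)),
            class = "ek_params")
}

#' @export
print.ek_params <- function(x, ...) {
  cat(sprintf(
    "ek_params: B0=%g beta0=%g c=%g alpha=%g delta=%g mu=%g m=%d\n",
    x$B0, x$beta0, x$c, x$alpha, x$delta, x$mu, x$m))
  invisible(x)
}

#' Kuramoto coupling
#'
#' `f(dphi) = (1 + cos(dphi)) / 2`: 1 at phase alignment, 0 at anti-phase,
#' even and 2-pi-periodic. Scales every phase-dependent benefit.
#'
#' @param delta_phi Phase difference in radians (vectorized).
#' @return Values in `[0, 1]`.
#' @export
coupling <- function(delta_phi) (1 + cos(delta_phi)) / 2

#' Payoff delivered along one directed edge
#'
#' The edge `tail -> head` pays the head player according to the label pair,
#' with `f = coupling(phi_tail - phi_head)`:
#' head C, tail C: `B0 f - c`; head C, tail N: `2 alpha beta0 f - c`;
#' head N, tail C: `2 (1 - alpha) beta0 f`; head N, tail N: 0.
#' At `alpha = 0.5` both mixed benefits reduce to `beta0 f`.
#'
#' @param head_label,tail_label `"C"` or `"N"` (vectorized).
#' @param head_k,tail_k Integer phase indices in `[0, m - 1]`.
#' @param params An [ek_params()].
#' @return Numeric payoff(s) to the head player.
#' @export
edge_payoff <- function(head_label, head_k, tail_label, tail_k, params) {
  stopifnot(inherits(params, "ek_params"))
  f <- coupling(2 * pi * (tail_k - head_k) / params$m)
  hc <- head_label == "C"
  tc <- tail_label == "C"
  ifelse(hc & tc, params$B0 * f - params$c,
  ifelse(hc & !tc, 2 * params$alpha * params$beta0 * f - params$c,
  ifelse(!hc & tc, 2 * (1 - params$alpha) * params$beta0 * f, 0)))
}

#' Hypothetical-switch 2x2 payoff matrix
#'
#' For a pair of players, each is given the hypothetical option of switching
#' to the other's strategy/phase; the cell is the row player's
#' [edge_payoff()] against the column player's chosen state. When both adopt
#' the same state the phase difference is 0, which produces the `f(0)` cells
#' of the condensed parameter matrix. Rows and columns are ordered
#' `(keep, switch)`.
#'
#' @param i_label,i_k Row player's label and phase index.
#' @param j_label,j_k Column player's label and phase index.
#' @param params An [ek_params()].
#' @return A 2x2 numeric matrix with attributes `pair` (`"CC"`, `"NN"` or
#'   `"mixed"`) and dimnames `keep`/`switch`.
#' @export
switch_game_matrix <- function(i_label, i_k, j_label, j_k, params) {
  opts_i <- list(c(i_label, i_k), c(j_label, j_k))
  opts_j <- list(c(j_label, j_k), c(i_label, i_k))
  mat <- matrix(0, 2, 2, dimnames = list(c("keep", "switch"), c("keep", "switch")))
  for (r in 1:2) for (cc in 1:2) {
    si <- opts_i[[r]]
    sj <- opts_j[[cc]]
    mat[r, cc] <- edge_payoff(si[1], as.numeric(si[2]), sj[1], as.numeric(sj[2]), params)
  }
  pair <- if (i_label == "C" && j_label == "C") "CC"
          else if (i_label == "N" && j_label == "N") "NN" else "mixed"
  attr(mat, "pair") <- pair
  mat
}

# Ordinal taxonomy of strict symmetric 2x2 games, keyed by the descending
# order of the row player's four payoffs R (both keep C-state), S (C against
# N), T (N against C) and P (both N). Swap-equivalence (relabelling which
# strategy is "kept") maps (R,S,T,P) -> (P,T,S,R), so names are canonicalized
# with R or T on top.
.game_names <- c(
  "R T P S" = "staghunt",
  "R T S P" = "concord",
  "R S T P" = "harmony",
  "R S P T" = "peace",
  "R P T S" = "assurance",
  "R P S T" = "coordination",
  "T R P S" = "dilemma",
  "T R S P" = "chicken",
  "T S R P" = "battle",
  "T S P R" = "hero",
  "T P R S" = "deadlock",
  "T P S R" = "compromise")

#' All game-type names used by the taxonomy
#' @return Character vector: the 12 strict symmetric ordinal game names plus
#'   `"cooperation"` (CC pairs) and `"neutral"` (NN pairs).
#' @export
game_type_names <- function() c(unname(.game_names), "cooperation", "neutral")

tie_levels <- function(v, tol) {
  # group values into tie classes (transitively within tol), level 1 = top
  o <- order(-v)
  lvl <- integer(length(v))
  lvl[o[1]] <- 1L
  for (idx in seq_along(o)[-1]) {
    prev <- o[idx - 1L]
    cur <- o[idx]
    lvl[cur] <- if (v[prev] - v[cur] <= tol) lvl[prev] else lvl[prev] + 1L
  }
  lvl
}

classify_rstp <- function(R, S, T, P, tol = 1e-9) {
  v <- c(R = R, S = S, T = T, P = P)
  if (any(!is.finite(v))) abort("payoff matrix has non-finite entries.")
  lvl <- tie_levels(v, tol)
  collapsed <- anyDuplicated(lvl) > 0
  # canonicalize: if the top tie class holds neither R nor T, relabel
  # keep <-> switch, i.e. (R,S,T,P) -> (P,T,S,R)
  if (!any(names(v)[lvl == 1L] %in% c("R", "T"))) {
    v <- c(R = unname(v["P"]), S = unname(v["T"]),
           T = unname(v["S"]), P = unname(v["R"]))
    lvl <- tie_levels(v, tol)
  }
  # descending order; ties resolved by the fixed preference R > T > S > P,
  # which reproduces the documented tie collapses (low lock -> deadlock,
  # mid hunt -> staghunt, mid harmony -> harmony)
  pref <- c(R = 1, T = 2, S = 3, P = 4)
  key <- paste(names(v)[order(lvl, pref)], collapse = " ")
  list(name = .game_names[[key]], collapsed = collapsed)
}

#' Classify a 2x2 game by its ordinal payoff pattern
#'
#' Maps the ordinal rank of the row player's four payoffs to a named game
#' type. CC pairs are always `"cooperation"` and NN pairs always `"neutral"`
#' (recognised from the `pair` attribute set by [switch_game_matrix()]).
#' Entries closer than `tol` are ties; the non-strict pattern is collapsed
#' onto the adjacent named game (`low lock` to deadlock, `mid hunt` to
#' staghunt, `mid harmony` to harmony) and flagged with `collapsed = TRUE`.
#'
#' @param mat A 2x2 matrix from [switch_game_matrix()] (or any row-player
#'   payoff matrix laid out `(keep, switch)` by `(keep, switch)`).
#' @param tol Tie tolerance on payoff differences.
#' @return A list with `name` and `collapsed`.
#' @export
classify_game <- function(mat, tol = 1e-9) {
  pair <- attr(mat, "pair")
  if (!is.null(pair) && pair == "CC") return(list(name = "cooperation", collapsed = FALSE))
  if (!is.null(pair) && pair == "NN") return(list(name = "neutral", collapsed = FALSE))
  if (!is.matrix(mat) || any(dim(mat) != 2)) abort("`mat` must be a 2x2 matrix.")
  # positional layout for a C row-player: s11 = S, s12 = R, s21 = P, s22 = T.
  # An N row-player produces the swap-equivalent layout, which canonicalizes
  # to the same name.
  classify_rstp(R = mat[1, 2], S = mat[1, 1], T = mat[2, 2], P = mat[2, 1],
                tol = tol)
}

#' Mixed-game type at a point of the (B0/c, beta/c, alpha) phase diagram
#'
#' Treats the realised mixed benefit `beta = beta0 f(dphi)` as a free axis
#' (in units of the cost `c`) and classifies the row player's ordinal game:
#' `R = B0/c - 1`, `S = 2 alpha beta/c - 1`, `T = 2 (1 - alpha) beta/c`,
#' `P = 0`.
#'
#' @param B0_over_c Joint benefit over cost.
#' @param beta_over_c Realised mixed benefit over cost.
#' @param alpha Asymmetry in `[0, 1]`.
#' @param tol Tie tolerance passed to the classifier.
#' @return Game-type name (character scalar).
#' @export
game_region <- function(B0_over_c, beta_over_c, alpha, tol = 1e-9) {
  classify_rstp(R = B0_over_c - 1,
                S = 2 * alpha * beta_over_c - 1,
                T = 2 * (1 - alpha) * beta_over_c,
                P = 0, tol = tol)$name
}

#' Rasterize a slice of the game-region phase diagram
#'
#' @param B0_over_c Scalar or vector of joint-benefit values (one axis).
#' @param beta_over_c Vector of mixed-benefit values (the other axis).
#' @param alpha Scalar or vector of asymmetries.
#' @return A tibble `(B0_over_c, beta_over_c, alpha, game)` over the grid.
#' @export
game_region_map <- function(B0_over_c, beta_over_c, alpha = 0.5) {
  grid <- expand.grid(B0_over_c = B0_over_c, beta_over_c = beta_over_c,
                      alpha = alpha, KEEP.OUT.ATTRS = FALSE)
  grid$game <- mapply(game_region, grid$B0_over_c, grid$beta_over_c, grid$alpha)
  out <- as_tibble(grid)
  class(out) <- c("ek_region_map", class(out))
  out
}

#' Plot a game-region slice
#' @param object A tibble from [game_region_map()].
#' @param ... Unused.
#' @return A ggplot raster of the game regions.
#' @export
autoplot.ek_region_map <- function(object, ...) {
  plot_game_regions(object)
}

#' @rdname autoplot.ek_region_map
#' @param map A tibble from [game_region_map()].
#' @export
plot_game_regions <- function(map) {
  yvar <- if (length(unique(map$alpha)) > 1) "alpha" else "B0_over_c"
  ggplot2::ggplot(map, ggplot2::aes(x = .data$beta_over_c,
                                    y = .data[[yvar]], fill = .data$game)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "beta / c", y = yvar, fill = "game type") +
    ggplot2::theme_minimal()
}
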