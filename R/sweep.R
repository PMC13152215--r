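#' Parameter sweep with seed replication
#'
#' Runs the Moran simulation across one parameter axis, replicating each value
#' over several seeds, and summarises a time-averaged metric (mean and
#' standard deviation across seeds — the study's convention is 10 seeds).
#'
#' @param g An [ek_graph()] interaction graph.
#' @param axis One of `"B0"`, `"alpha"`, `"beta0_ratio"`, `"m"`, `"delta"`,
#'   `"mu"`. Sweeping `B0` keeps `beta0/B0` fixed at the baseline ratio.
#' @param values Numeric vector of axis values.
#' @param seeds Integer vector of seeds (one run per value x seed).
#' @param params Baseline [ek_params()].
#' @param steps Steps per run.
#' @param sample_every Sampling stride.
#' @param metric `"f_comm"` (time-averaged communicative fraction), `"chi"`
#'   or `"lambda"` (require `communities`), or `"monomorphic"` (fraction of
#'   sampled steps with all-C or all-N labels).
#' @param communities Optional `(node, community)` tibble for the chimera
#'   metrics.
#' @return A tibble `(value, mean, sd, n_seeds)` of class `ek_sweep`, with the
#'   per-run values in the `runs` attribute.
#' @export
run_sweep <- function(g, axis, values, seeds = 1:10, params = ek_params(),
                      steps = 8e5, sample_every = 800L,
                      metric = c("f_comm", "chi", "lambda", "monomorphic"),
                      communities = NULL) {
  metric <- match.arg(metric)
  axis <- match.arg(axis, c("B0", "alpha", "beta0_ratio", "m", "delta", "mu"))
  if (metric %in% c("chi", "lambda") && is.null(communities)) {
    abort("chimera metrics need a `communities` assignment.")
  }
  ratio <- params$beta0 / params$B0
  with_axis <- function(v) {
    p <- unclass(params)
    if (axis == "B0") { p$B0 <- v; p$beta0 <- ratio * v }
    else if (axis == "beta0_ratio") p$beta0 <- v * p$B0
    else if (axis == "m") p$m <- as.integer(v)
    else p[[axis]] <- v
    do.call(ek_params, p)
  }
  runs <- purrr::map_dfr(values, function(v) {
    pv <- with_axis(v)
    purrr::map_dfr(seeds, function(s) {
      sim <- run_simulation(g, pv, steps = steps, seed = s,
                            sample_every = sample_every)
      val <- switch(metric,
        f_comm = mean(sim$metrics$f_comm),
        monomorphic = glance(sim)$fraction_monomorphic,
        chi = chimera_index(community_order_series(sim, communities)),
        lambda = metastability_index(community_order_series(sim, communities)))
      tibble(value = v, seed = s, metric = val)
    })
  })
  out <- runs %>%
    group_by(.data$value) %>%
    summarise(mean = mean(.data$metric),
              sd = if (dplyr::n() > 1) stats::sd(.data$metric) else 0,
              n_seeds = dplyr::n(), .groups = "drop")
  attr(out, "runs") <- runs
  attr(out, "metric") <- metric
  attr(out, "axis") <- axis
  class(out) <- c("ek_sweep", class(out))
  out
}

#' @export
autoplot.ek_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = attr(object, "axis"), y = attr(object, "metric")) +
    ggplot2::theme_minimal()
}
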