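#' Plot the expected-utility profile of an optimised design
#'
#' Draws the expected utility of the best design of each trial size,
#' \eqn{\mathcal{G}(n, z_\alpha^*(n))}, over a range of `n`, marking the
#' optimum; the dashed horizontal line is the no-trial alternative.
#' Decorative: figures are not part of the tested surface.
#'
#' @param object A `voi_design` from [optimize_design()].
#' @param n_range Range of sample sizes to draw (defaults to up to four
#'   times the optimum, within feasibility).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voi_design
#' @export
autoplot.voi_design <- function(object, n_range = NULL, ...) {
  model <- object$model
  n_max <- 2 * floor(model$rho * model$N / 2)
  if (is.null(n_range)) {
    hi <- if (object$no_trial) n_max else min(max(4 * object$n_star, 20), n_max)
    n_range <- c(2, hi)
  }
  ns <- seq(n_range[1], n_range[2], length.out = 200)
  df <- tibble(n = ns, g = g_profile(model, ns) / 1e6)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = n, y = g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$g_no_trial / 1e6, linetype = "dashed") +
    ggplot2::labs(
      x = "total trial sample size, n",
      y = "expected utility ($ million)",
      title = "Expected utility at the optimal threshold for each n"
    )
  if (!object$no_trial) {
    p <- p + ggplot2::annotate("point",
      x = object$n_star,
      y = g_profile(model, object$n_star) / 1e6, size = 2
    )
  }
  p
}

#' Plot operating-characteristic sweeps
#'
#' Faceted view of a [sweep_designs()] table: optimal sample size, type I
#' and type II error rates, and expected utility against population size
#' (log scale), one line per treatment cost. Decorative: figures are not
#' part of the tested surface.
#'
#' @param object A `voi_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voi_sweep
#' @export
autoplot.voi_sweep <- function(object, ...) {
  long <- object |>
    dplyr::mutate(g_star = g_star / 1e6) |>
    dplyr::select(N, c2, n_star, alpha_star, beta_star, g_star) |>
    tidyr::pivot_longer(c(n_star, alpha_star, beta_star, g_star),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = factor(metric,
      levels = c("n_star", "alpha_star", "beta_star", "g_star"),
      labels = c(
        "optimal n*", "type I error rate", "type II error rate",
        "expected utility ($M)"
      )
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = N, y = value,
    colour = factor(c2), group = factor(c2)
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "population size, N (log scale)", y = NULL,
      colour = "treatment cost c2 ($)"
    )
}
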