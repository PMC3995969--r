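# ggplot2 displays for the main result types.

#' @export
autoplot.seasonal_map <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(cols = c("rainy", "cold_dry", "hot_dry", "whole_period"),
                        names_to = "season", values_to = "net_change") |>
    dplyr::mutate(season = factor(.data$season,
                                  levels = c("rainy", "cold_dry", "hot_dry",
                                             "whole_period")))
  ggplot2::ggplot(long, ggplot2::aes(.data$x_km, .data$y_km,
                                     fill = .data$net_change)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~season) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "forestgreen", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  fill = "net change\n(log10/month)",
                  title = "Seasonal net population change") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mcmc_chain <- function(object, ...) {
  long <- purrr::imap(object$chains, function(m, i) {
    tibble::as_tibble(m) |>
      dplyr::mutate(iteration = dplyr::row_number(), chain = factor(i))
  }) |>
    purrr::list_rbind() |>
    tidyr::pivot_longer(cols = dplyr::all_of(param_names),
                        names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(title = "MCMC traces (kept draws)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.moran_fit <- function(object, ...) {
  d <- object$decomposition
  lim <- range(c(d$y_t, d$y_t1))
  ggplot2::ggplot(d, ggplot2::aes(.data$y_t, .data$y_t1)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = object$b,
                         colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$a, linetype = 3) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(
      x = expression(y[t] ~ (log[10] ~ abundance)),
      y = expression(y[t + 1]),
      title = "Moran curve",
      subtitle = sprintf("fertility line at b = %.3g; density dependence starts at a = %.3g",
                         object$b, object$a)
    ) +
    ggplot2::theme_minimal()
}

#' Monthly population losses by site
#'
#' Mean total losses (di_hat + dd) per site and month against the fertility
#' level: months where the loss curve sits above the fertility line are
#' months of local decline.
#'
#' @param fit A `moran_fit`.
#' @return A ggplot.
#' @export
plot_losses <- function(fit) {
  d <- fit$decomposition |>
    dplyr::group_by(.data$site, .data$t) |>
    dplyr::summarise(losses = mean(.data$di_hat + .data$dd), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$losses, colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = fit$b, linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = unique(d$t)) +
    ggplot2::labs(x = "month", y = "mean losses (di + dd, log10 scale)",
                  title = "Population losses against the fertility level") +
    ggplot2::theme_minimal()
}
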