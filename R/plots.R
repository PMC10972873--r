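#' Heat map of ensemble BiEntropy over (K, |sigma*|)
#'
#' Tiles the mean (or variance) of the ensemble BiEntropy over the in-degree
#' and the weight-parameter magnitude, one facet per balance sign — the
#' standard view of the order-disorder phase diagram.
#'
#' @param object An `rbn_dynamics_summary` (see [summarize_dynamics()]).
#' @param fill `"mean_hb"` (default) or `"var_hb"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rbn_dynamics_summary <- function(object, fill = c("mean_hb", "var_hb"), ...) {
  fill <- match.arg(fill)
  df <- dplyr::mutate(object,
                      mag = abs(.data$sigma_star),
                      sign = factor(ifelse(.data$sigma_star < 0, "b < 0", "b > 0")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mag, y = factor(.data$k),
                                   fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(n ~ sign) +
    ggplot2::scale_fill_viridis_c(option = if (fill == "mean_hb") "turbo" else "magma") +
    ggplot2::labs(x = "|sigma*|", y = "K",
                  fill = if (fill == "mean_hb") "mean BiEntropy" else "BiEntropy variance")
}

#' Stacked attractor-category fractions along the balance axis
#'
#' @param summary An `rbn_dynamics_summary`.
#' @return A ggplot: stacked category percentages vs `b`, faceted by (n, k)
#'   and balance sign.
#' @export
plot_attractor_fractions <- function(summary) {
  df <- summary |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"),
                        names_to = "category", values_to = "pct",
                        names_prefix = "pct_") |>
    dplyr::mutate(
      category = factor(.data$category, levels = attractor_categories()),
      sign = factor(ifelse(.data$sigma_star < 0, "b < 0", "b > 0"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$b), y = .data$pct,
                                   fill = .data$category)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_grid(n + k ~ sign) +
    ggplot2::labs(x = "|b|", y = "% of reservoirs", fill = "attractor")
}

#' Performance curves along the balance axis
#'
#' @param object An `rbn_performance_summary` (see [summarize_performance()]).
#' @param ... Unused.
#' @return A ggplot: mean correlation with a one-standard-deviation ribbon vs
#'   `|b|`, colored by difficulty, faceted by task and balance sign.
#' @exportS3Method ggplot2::autoplot
autoplot.rbn_performance_summary <- function(object, ...) {
  df <- dplyr::mutate(object,
                      sign = factor(ifelse(.data$b < 0, "b < 0", "b > 0")),
                      difficulty = factor(.data$difficulty))
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$b), y = .data$mean_corr,
                                   color = .data$difficulty,
                                   fill = .data$difficulty,
                                   group = .data$difficulty)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_corr - .data$sd_corr,
                                      ymax = .data$mean_corr + .data$sd_corr),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(task + n ~ sign) +
    ggplot2::labs(x = "|b|", y = "Corr(y, T)")
}

#' Best performance per in-degree
#'
#' @param object An `rbn_best_k` table (see [summarize_best_k()]).
#' @param ... Unused.
#' @return A ggplot: mean correlation at the optimal balance vs K.
#' @exportS3Method ggplot2::autoplot
autoplot.rbn_best_k <- function(object, ...) {
  df <- dplyr::mutate(object,
                      sign = factor(ifelse(.data$sign < 0, "b < 0", "b > 0")),
                      difficulty = factor(.data$difficulty))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mean_corr,
                                   color = .data$difficulty,
                                   group = .data$difficulty)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_corr - .data$sd_corr,
                                          ymax = .data$mean_corr + .data$sd_corr)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(task ~ sign) +
    ggplot2::labs(x = "K", y = "Corr(y, T) at b_opt")
}
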