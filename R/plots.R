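# ggplot2 displays for the main result types

#' Plot a differential-abundance result
#'
#' Scatter of per-clone frequencies in sample A versus sample B on log-log
#' axes, coloured by classification; zero counts are displayed at half a
#' template. The familiar repertoire-comparison view: clones off the
#' diagonal and coloured were called expanded or contracted.
#'
#' @param object A `diffab_result` from [run_diffab()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffab_result
#' @export
autoplot.diffab_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      fa = pmax(.data$k_A, 0.5) / .data$n_A,
      fb = pmax(.data$k_B, 0.5) / .data$n_B
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$fa, .data$fb,
                                   colour = .data$classification)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(
      expanded = "#D55E00", contracted = "#0072B2",
      not_significant = "grey35", not_tested = "grey80"), drop = FALSE) +
    ggplot2::labs(x = "clone frequency, sample A",
                  y = "clone frequency, sample B",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted dispersion model over its training bins
#'
#' Residual variance per `k_total` bin (points, area by number of clones)
#' with the fitted curve `(b log k + a)^2`.
#'
#' @param object A fitted [dispersion_model()] produced by
#'   [fit_dispersion()] (the training table travels in its provenance).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dispersion_model
#' @export
autoplot.dispersion_model <- function(object, ...) {
  check_fitted(object)
  tab <- object$provenance$table
  if (is.null(tab)) {
    stop_domain("this dispersion model carries no training table to plot",
                "diffclone_state_error")
  }
  grid <- tibble::tibble(
    k_total = exp(seq(log(min(tab$k_total)), log(max(tab$k_total)),
                      length.out = 200))
  )
  grid$v <- predict_variance(object, grid$k_total)
  ggplot2::ggplot(tab, ggplot2::aes(.data$k_total, .data$residual_var)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_obs),
                        alpha = 0.5, colour = "grey30") +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$k_total, .data$v),
                       colour = "#D55E00", linewidth = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pooled clone count k_total",
                  y = "residual count variance",
                  size = "clones in bin") +
    ggplot2::theme_minimal()
}

#' Plot a power grid
#'
#' Detection probability versus baseline clone frequency, one line per
#' expected fold change, with Monte-Carlo standard-error ribbons.
#'
#' @param object A `power_grid` from [estimate_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_grid
#' @export
autoplot.power_grid <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(fold = factor(.data$fold_change))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_mid, .data$power,
                                   colour = .data$fold, group = .data$fold)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$power - .data$se, 0),
                                      ymax = pmin(.data$power + .data$se, 1),
                                      fill = .data$fold),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "baseline clone frequency (sample A)",
                  y = "power (P(classified expanded))",
                  colour = "fold change", fill = "fold change") +
    ggplot2::theme_minimal()
}
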