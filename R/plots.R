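#' Plot a concentration-time profile
#'
#' @param object A `pk_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pk_profile
#' @export
autoplot.pk_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_h,
                                       .data$conc_ng_per_ml)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)")
}

#' Goodness-of-fit plot for a population fit
#'
#' Observed concentrations against population (PRED) and individual
#' (IPRED) predictions on the log scale, with the identity line.
#'
#' @param object A `pru_fit` object.
#' @param dataset The fitted dataset.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pru_fit
#' @export
autoplot.pru_fit <- function(object, dataset, ...) {
  res <- compute_cwres(object, dataset)
  long <- tidyr::pivot_longer(res, c("pred", "ipred"),
                              names_to = "prediction",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$dv)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "orange") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~prediction) +
    ggplot2::labs(x = "Predicted (ng/mL)", y = "Observed (ng/mL)")
}

#' Residual diagnostic panels
#'
#' Conditional weighted residuals against population predictions and
#' against time after dose, with a zero reference line.
#'
#' @param object A `pru_residuals` tibble from [compute_cwres()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pru_residuals
#' @export
autoplot.pru_residuals <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("pred", "time_after_dose"),
                              names_to = "against", values_to = "x")
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$cwres)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, colour = "orange") +
    ggplot2::geom_smooth(se = FALSE, method = "loess",
                         formula = y ~ x, colour = "orange") +
    ggplot2::facet_wrap(~against, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "CWRES")
}

#' Visual predictive check plot
#'
#' Observed percentiles (points/lines) over the simulated across-replicate
#' bands (ribbons), by time bin and tracked percentile.
#'
#' @param object A `pru_vpc` tibble from [vpc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pru_vpc
#' @export
autoplot.pru_vpc <- function(object, ...) {
  d <- dplyr::mutate(object,
                     pct = factor(sprintf("p%g", 100 * .data$prob)))
  ggplot2::ggplot(d, ggplot2::aes(.data$bin, group = .data$pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi,
                                      fill = .data$pct), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$pct)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$pct)) +
    ggplot2::labs(x = "Bin", y = "Concentration (ng/mL)",
                  colour = "Percentile", fill = "Percentile")
}

#' Plot an age-by-dose exposure grid
#'
#' Typical profiles faceted by age, coloured by per-kg dose, with the
#' adult reference profile overlaid when supplied.
#'
#' @param grid A `dose_grid` from [simulate_dose_grid()].
#' @param adult Optional [adult_reference()] whose profile is overlaid.
#' @return A ggplot object.
#' @export
plot_dose_grid <- function(grid, adult = NULL) {
  p <- ggplot2::ggplot(grid$profiles,
                       ggplot2::aes(.data$time_h, .data$conc_ng_per_ml,
                                    colour = factor(.data$dose_mg_per_kg))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~age_years) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)",
                  colour = "Dose (mg/kg)")
  if (!is.null(adult)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::mutate(adult$profile, dose_mg_per_kg = NA),
      ggplot2::aes(.data$time_h, .data$conc_ng_per_ml),
      colour = "orange", inherit.aes = FALSE)
  }
  p
}
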