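# ggplot2 visualisations for the main result types.

#' Plot a dose field
#'
#' Cycle-averaged power density versus radius, on a log y scale.
#'
#' @param object A `dose_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_field
#' @export
autoplot.dose_field <- function(object, ...) {
  df <- tibble::tibble(radius_mm = object$center_radius * 1e3,
                       pbar_uW_mm3 = convert_power_density(object$pbar,
                                                           "W/m3", "uW/mm3"))
  ggplot2::ggplot(df, ggplot2::aes(.data$radius_mm, .data$pbar_uW_mm3)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "radius (mm)",
                  y = expression(bar(p) ~ (mu * W / mm^3)),
                  title = "Cycle-averaged cytoplasm power density")
}

#' Plot a death curve
#'
#' Death radius versus treatment duration, optionally on a log time axis —
#' the axis on which the experimental radii are approximately linear.
#'
#' @param object A `death_curve`.
#' @param log_time Use a log10 duration axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot death_curve
#' @export
autoplot.death_curve <- function(object, log_time = TRUE, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$duration_ms, .data$radius_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "treatment duration (ms)", y = "death radius (mm)")
  if (log_time) p <- p + ggplot2::scale_x_log10()
  prm <- attr(object, "params")
  if (!is.null(prm)) {
    p <- p + ggplot2::ggtitle(sprintf("%s model: Pth = %g uW/mm3, Wth = %g uJ/mm3",
                                      prm$model, prm$pth, prm$wth))
  }
  p
}

#' Plot an experiment dataset (mean +/- SD per duration)
#'
#' @param object A `plasma_experiment`.
#' @param log_time Use a log10 duration axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plasma_experiment
#' @export
autoplot.plasma_experiment <- function(object, log_time = TRUE, ...) {
  smry <- dataset_summary(object)
  p <- ggplot2::ggplot(smry, ggplot2::aes(.data$duration_ms,
                                          .data$mean_radius_mm)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_radius_mm - .data$sd_radius_mm,
      ymax = .data$mean_radius_mm + .data$sd_radius_mm), width = 0.05) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "treatment duration (ms)", y = "death radius (mm)")
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a threshold-fit objective surface
#'
#' @param object A `threshold_fit`.
#' @param ... Unused.
#' @return A ggplot object (coarse-grid objective heat map with the best
#'   point marked).
#' @method autoplot threshold_fit
#' @export
autoplot.threshold_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$pth, .data$wth,
                                            fill = log10(.data$objective_mm2 + 1e-12))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, fill = NA, colour = "red",
                        shape = 4, size = 3) +
    ggplot2::labs(x = expression(P[th] ~ (mu * W / mm^3)),
                  y = expression(W[th] ~ (mu * J / mm^3)),
                  fill = "log10 SSR")
}

#' Plot an effective-Pth profile
#'
#' @param object A `pth_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pth_profile
#' @export
autoplot.pth_profile <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$converged)
  ggplot2::ggplot(df, ggplot2::aes(.data$duration_ms, .data$effective_pth)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 17, size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "treatment duration (ms)",
                  y = expression(effective ~ P[th] ~ (mu * W / mm^3)))
}
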