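#' Plot a force-displacement curve from an experiment log
#'
#' @param object An `experiment_log`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.experiment_log <- function(object, ...) {
  d <- object$records
  d$position_um <- d$position_nm / 1000
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position_um,
                                  y = .data$force_uN)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Actuator position (µm)",
                  y = "Force (µN)",
                  title = sprintf("Force–displacement (%s)",
                                  object$status)) +
    ggplot2::theme_minimal()
}

#' Plot a stress-strain curve
#'
#' @param object A [stress_strain_curve()].
#' @param region Optional linear region from [select_linear_region()],
#'   highlighted when given.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stress_strain_curve <- function(object, region = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$strain_pct,
                                            y = .data$stress_MPa)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Strain (%)", y = "Stress (MPa)") +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    idx <- region$start:region$end
    p <- p + ggplot2::geom_line(data = object[idx, ], colour = "red")
  }
  p
}

#' Plot the two strain pathways against each other
#'
#' Shows landmark (tissue) strain, grip (actuator) strain and their
#' difference (slip) per step; divergence of the two pathways is the
#' signature of grip slippage.
#'
#' @param object A [strain_series()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strain_series <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           cols = c("landmark_strain_pct",
                                    "grip_strain_pct", "slip_strain_pct"),
                           names_to = "pathway", values_to = "strain_pct")
  d$pathway <- sub("_strain_pct$", "", d$pathway)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$strain_pct,
                                  colour = .data$pathway)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Step", y = "Strain (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot windowed creep rates
#'
#' Landmark versus grip displacement rates per window; a grip rate
#' pulling away from the landmark rate indicates slip taking over.
#'
#' @param object A `creep_profile` from [creep_rates()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.creep_profile <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           cols = c("landmark_rate_um_per_s",
                                    "grip_rate_um_per_s"),
                           names_to = "pathway", values_to = "rate")
  d$pathway <- ifelse(grepl("landmark", d$pathway), "landmark", "grip")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_start_s, y = .data$rate,
                                  colour = .data$pathway)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (s)", y = "Displacement rate (µm/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Display a synthetic snapshot
#'
#' @param object An `extensometer_frame`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.extensometer_frame <- function(object, ...) {
  d <- expand.grid(y = seq_len(object$height_px),
                   x = seq_len(object$width_px))
  d$value <- as.vector(object$pixels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
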