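#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a motion profile
#'
#' Velocity, acceleration, jerk and position traces of one stimulus epoch.
#'
#' @param object A `motion_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motion_profile
#' @export
autoplot.motion_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("position", "velocity", "acceleration", "jerk"),
                            names_to = "trace", values_to = "value")
  df$trace <- factor(df$trace,
                     levels = c("position", "velocity", "acceleration",
                                "jerk"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trace, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Gaussian-velocity motion profile")
}

#' Plot a PSTH matrix as a direction-by-time heatmap
#'
#' @param object A `psth_matrix`.
#' @param smoothed Show smoothed (default) or raw rates.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psth_matrix
#' @export
autoplot.psth_matrix <- function(object, smoothed = TRUE, ...) {
  df <- tidy(object)
  df$value <- if (smoothed) df$smoothed_rate else df$rate
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$direction_index,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "spikes/s") +
    ggplot2::labs(x = "time (s)", y = "direction index",
                  title = sprintf("PSTH: %s [%s]", object$neuron_id,
                                  object$condition))
}

#' Plot observed vs fitted responses of a spatiotemporal model fit
#'
#' Overlays the fitted model on the observed smoothed PSTH for the
#' strongest-responding directions.
#'
#' @param object An `st_model_fit`.
#' @param n_directions How many directions to show (by peak response).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot st_model_fit
#' @export
autoplot.st_model_fit <- function(object, n_directions = 6, ...) {
  sel <- order(apply(object$observed, 1, max),
               decreasing = TRUE)[seq_len(n_directions)]
  df <- purrr::list_rbind(purrr::map(sel, function(d) {
    tibble::tibble(direction_index = d, time_s = object$times,
                   observed = object$observed[d, ],
                   fitted = object$fitted[d, ])
  }))
  df <- tidyr::pivot_longer(df, c("observed", "fitted"),
                            names_to = "kind", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$rate,
                                   linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~direction_index, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "rate (spikes/s)",
                  title = sprintf("%s model fit: R2 = %.3f",
                                  object$model_kind, object$r2))
}

#' Plot preferred directions of a screened population
#'
#' Azimuth-elevation scatter of preferred directions, the standard view of a
#' population's spatial-preference distribution.
#'
#' @param screen Tibble from [screen_population()].
#' @return A ggplot.
#' @export
plot_preferred_directions <- function(screen) {
  df <- screen[is.finite(screen$pref_azimuth_deg), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$pref_azimuth_deg,
                                   .data$pref_elevation_deg,
                                   size = .data$ddi)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 360, 90)) +
    ggplot2::scale_y_continuous(limits = c(-90, 90),
                                breaks = seq(-90, 90, 45)) +
    ggplot2::labs(x = "preferred azimuth (deg)",
                  y = "preferred elevation (deg)",
                  title = "Population preferred directions")
}
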