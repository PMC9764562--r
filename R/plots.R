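#' Plot a trajectory
#'
#' Path in arena coordinates with the arena wall drawn as a circle.
#'
#' @param object A [trajectory()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory <- function(object, ...) {
  r <- attr(object, "arena_radius")
  wall <- tibble::tibble(a = seq(0, 2 * pi, length.out = 200))
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.2, colour = "grey30") +
    ggplot2::geom_path(data = tibble::tibble(x = r * cos(wall$a),
                                             y = r * sin(wall$a)),
                       colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a firing-rate map
#'
#' Heat map of the smoothed rate over valid bins.
#'
#' @param object A `"rate_map"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(dplyr::filter(df, .data$valid),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Hz", option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a down-sampling result
#'
#' Distribution of the subsample metric means.
#'
#' @param object A `"downsampling_result"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.downsampling_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$mean)),
                  ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "subsample mean", y = "count",
                  subtitle = sprintf("modulation probability = %.3f",
                                     object$modulation_probability)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
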