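#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rotation-angle time series
#'
#' Angle against time with optional horizontal guides at the angles of
#' reference states (e.g. 0 and 63 degrees for the inward- and outward-open
#' structures).
#'
#' @param object An `angle_series` from [rotation_series()].
#' @param guides Named numeric vector of guide angles (degrees).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot angle_series
#' @export
autoplot.angle_series <- function(object, guides = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_ns, y = .data$angle_deg)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(x = "time (ns)",
                  y = "ring rotation angle (deg, CCW from extracellular)")
  if (!is.null(guides)) {
    p <- p + ggplot2::geom_hline(yintercept = unname(guides),
                                 linetype = "dashed", color = "grey40")
  }
  p
}

#' Plot a seam hydrogen-bond time series
#'
#' Raw per-frame counts (points) and the moving average (line), coloured by
#' seam state when [classify_seam_state()] has been applied.
#'
#' @param object An `hbond_series` from [hbond_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hbond_series
#' @export
autoplot.hbond_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$count),
                        alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "time (ns)", y = "seam backbone H-bonds")
  if ("state" %in% names(df)) {
    p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed,
                                        color = .data$state, group = 1))
  } else {
    p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                           color = "#b2182b")
  }
}

#' Plot an in-plane track
#'
#' The path of the tracked center in the membrane plane, coloured by time.
#'
#' @param object A `track_series` from [track_center()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot track_series
#' @export
autoplot.track_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               color = .data$time_ns)) +
    ggplot2::geom_path() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "in-plane x (A)", y = "in-plane y (A)",
                  color = "time (ns)")
}

#' Plot a 2D density map
#'
#' @param object A [density_map2d()].
#' @param ... Unused.
#' @return A ggplot raster of the map.
#' @method autoplot density_map2d
#' @export
autoplot.density_map2d <- function(object, ...) {
  n <- nrow(object$values)
  ax <- (seq_len(n) - (n %/% 2L + 1L)) * object$pixel_size
  df <- tidyr::expand_grid(x = ax, y = ax)
  df$value <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (A)", y = "y (A)", fill = "intensity")
}

#' @importFrom rlang .data
NULL
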