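#' Plot an MSD curve
#'
#' @param object An `msd_curve` from [msd()].
#' @param n_lags If non-`NULL`, overlays the first-`n_lags` diffusion fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msd_curve <- function(object, n_lags = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "lag (frames)", y = expression(MSD ~ (px^2)))
  if (!is.null(n_lags)) {
    fit <- fit_diffusion(object, n_lags = n_lags)
    p <- p + ggplot2::geom_abline(intercept = fit$intercept,
                                  slope = fit$slope, linetype = 2) +
      ggplot2::ggtitle(sprintf("D = %.4g px²/frame", fit$D))
  }
  p
}

#' Plot tracks in the image plane
#'
#' @param tracks A `vt_tracks` tibble.
#' @return A ggplot object (y axis reversed to match image rows).
#' @export
plot_tracks <- function(tracks) {
  ggplot2::ggplot(tracks, ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$track_id,
                                       colour = factor(.data$track_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot a radial fraction-at-distance profile
#'
#' @param object A `radial_profile` from [fraction_at_distance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$bin),
                                       y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "annulus (centroid → edge)", y = "fraction")
}

#' Plot a turning-angle histogram
#'
#' @param angles Tibble from [turning_angles()].
#' @param binwidth Histogram bin width, degrees.
#' @return A ggplot object.
#' @export
plot_turning_angles <- function(angles, binwidth = 10) {
  ggplot2::ggplot(angles, ggplot2::aes(x = .data$angle)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            colour = "white") +
    ggplot2::labs(x = "turning angle (degrees)", y = "count")
}
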