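#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a smoothed OKR gain map in Mercator-style coordinates
#'
#' @param gain_map Tibble with `azimuth`, `elevation`, `gain` (e.g. from
#'   [vmf_kernel_smooth()]).
#' @param centres Optional tibble of stimulus centres to overlay.
#' @return A ggplot object.
#' @export
plot_gain_map <- function(gain_map, centres = NULL) {
  p <- ggplot2::ggplot(gain_map, ggplot2::aes(
    x = .data$azimuth, y = .data$elevation, fill = .data$gain
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "OKR gain") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(centres)) {
    p <- p + ggplot2::geom_point(
      data = centres,
      ggplot2::aes(x = .data$azimuth, y = .data$elevation),
      inherit.aes = FALSE, shape = 21, fill = "white", size = 2
    )
  }
  p
}

#' @rdname fit_bimodal_vmf
#' @param object An `okr_vmf_fit`.
#' @export
autoplot.okr_vmf_fit <- function(object, ...) {
  grid <- tidyr::expand_grid(
    azimuth = seq(-180, 180, by = 2.5),
    elevation = seq(-90, 90, by = 2.5)
  )
  grid$gain <- vmf_sum_eval(object$model, grid$azimuth, grid$elevation)
  plot_gain_map(grid, centres = object$data) +
    ggplot2::ggtitle("Fitted bimodal von Mises-Fisher gain surface")
}

#' @rdname fit_piecewise_sinusoid
#' @param object An `okr_sinusoid_fit`.
#' @export
autoplot.okr_sinusoid_fit <- function(object, ...) {
  tr <- object$trace
  fit_df <- tibble::tibble(
    time_s = object$time_used, fitted = object$fitted,
    isi = factor(object$isi_of)
  )
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$angle_deg)) +
    ggplot2::geom_line(colour = "grey50", linewidth = 0.3) +
    ggplot2::geom_line(
      data = fit_df,
      ggplot2::aes(y = .data$fitted, group = .data$isi),
      colour = "#1b9e77", linewidth = 0.7
    ) +
    ggplot2::labs(x = "time (s)", y = "eye position (deg)",
                  title = sprintf("piecewise sinusoid fit: c1 = %.2f deg, R^2 = %.2f",
                                  object$c1, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname frequency_tuning
#' @param object An `okr_tuning_fit`.
#' @export
autoplot.okr_tuning_fit <- function(object, ...) {
  if (object$kind == "frequency") {
    d <- dplyr::summarise(
      dplyr::group_by(object$data, .data$location_id, .data$spatial_frequency),
      gain = mean(.data$gain), .groups = "drop"
    )
    ggplot2::ggplot(d, ggplot2::aes(
      x = .data$spatial_frequency, y = .data$gain,
      colour = factor(.data$location_id)
    )) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "spatial frequency (cycles/deg)", y = "OKR gain",
                    colour = "location") +
      ggplot2::theme_minimal()
  } else {
    d <- dplyr::summarise(
      dplyr::group_by(object$data, .data$location_id, .data$size),
      gain = mean(.data$gain), .groups = "drop"
    )
    ggplot2::ggplot(d, ggplot2::aes(
      x = .data$size, y = .data$gain, colour = factor(.data$location_id)
    )) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "stimulus size (fraction of sphere)", y = "OKR gain",
                    colour = "location") +
      ggplot2::theme_minimal()
  }
}

#' @rdname permutation_test_elevation
#' @param object An `okr_permutation_test`.
#' @export
autoplot.okr_permutation_test <- function(object, ...) {
  d <- tibble::tibble(statistic = object$permutation_statistics)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#d95f02",
                        linewidth = 1) +
    ggplot2::labs(
      x = "permutation statistic",
      title = sprintf("p = %.3g (%d permutations)", object$p_value,
                      object$n_permutations)
    ) +
    ggplot2::theme_minimal()
}
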