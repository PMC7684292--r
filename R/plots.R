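# ggplot2 displays for the main result types.

#' Plot a redox-ratio histogram
#'
#' @param object a [mean_redox()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot redox_summary
#' @export
autoplot.redox_summary <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = h$bin_hi[1] - h$bin_lo[1],
                      fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$mean_rr, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "max-projected NADH/FAD redox ratio",
                  y = "pixels",
                  title = sprintf("mean RR %.3f ± %.4f (SE)",
                                  object$mean_rr, object$se)) +
    ggplot2::theme_minimal()
}

#' Plot a longitudinal reflectivity profile
#'
#' Reflectivity against depth, with detected layer boundaries overlaid
#' when supplied.
#'
#' @param object an [compute_lrp()] profile.
#' @param boundaries optional [detect_boundaries()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lrp
#' @export
autoplot.lrp <- function(object, boundaries = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$depth_um,
                                    y = .data$reflectivity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (µm)", y = "reflectivity (AU)") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    b <- tidy(boundaries)
    p <- p + ggplot2::geom_vline(data = b,
                                 ggplot2::aes(xintercept = .data$depth_um),
                                 linetype = 2, colour = "red")
  }
  p
}

#' Plot an ERG trace
#' @param object an [erg_trace()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot erg_trace
#' @export
autoplot.erg_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_ms, y = .data$voltage_uV)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time (ms)", y = "voltage (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a scotopic intensity series
#' @param object a [build_intensity_series()] result.
#' @param ... unused.
#' @return a ggplot (a- and b-wave amplitude vs log flash intensity).
#' @method autoplot intensity_series
#' @export
autoplot.intensity_series <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("a_amp", "b_amp"), names_to = "wave",
                        values_to = "amplitude_uV")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$intensity,
                                     y = .data$amplitude_uV,
                                     colour = .data$wave)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "flash intensity (mcd·s/m²)",
                  y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a spider profile
#' @param object a [build_spider()] result.
#' @param ... unused.
#' @return a ggplot of nuclei-row counts vs signed distance from the ONH.
#' @method autoplot spider_profile
#' @export
autoplot.spider_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$location_um, y = .data$n_rows)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$n_rows - .data$se,
                                          ymax = .data$n_rows + .data$se)) +
    ggplot2::labs(x = "distance from ONH (µm, + superior)",
                  y = "photoreceptor nuclei rows") +
    ggplot2::theme_minimal()
}
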