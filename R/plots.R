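#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gridded field
#'
#' @param object A `scalar_field2d`.
#' @param ... Unused.
#' @return A ggplot raster of the field values (missing bins blank).
#' @method autoplot scalar_field2d
#' @export
autoplot.scalar_field2d <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  fill = if (object$mode == "normalized-density")
                    "probability" else "value") +
    ggplot2::theme_minimal()
}

#' Plot a pair membrane-modulation profile
#'
#' @param object A `pair_profile`.
#' @param what `"order"` or `"thickness"`.
#' @param ... Unused.
#' @return A ggplot raster over (r, d).
#' @method autoplot pair_profile
#' @export
autoplot.pair_profile <- function(object, what = c("order", "thickness"),
                                  ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$d,
                                   fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "protomer distance r (nm)",
                  y = "lipid position d (nm)", fill = what) +
    ggplot2::theme_minimal()
}

#' Plot an interface frequency posterior
#'
#' @param object An `interface_freq_posterior`.
#' @param ... Unused.
#' @return A ggplot point-range of posterior means with credible bars.
#' @method autoplot interface_freq_posterior
#' @export
autoplot.interface_freq_posterior <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$interface,
                                                  -.data$estimate),
                                   .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "interface fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an azimuthal order/thickness profile
#'
#' @param profile Result of [helix_azimuth_profile()] or
#'   [summarise_profiles()].
#' @param what `"order"` or `"thickness"`.
#' @return A ggplot line with helix-COM azimuth marks.
#' @export
plot_azimuth_profile <- function(profile, what = c("order", "thickness")) {
  what <- match.arg(what)
  ycol <- if ("mean_order" %in% names(profile)) {
    if (what == "order") "mean_order" else "mean_thickness"
  } else what
  marks <- attr(profile, "helix_marks")
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(.data$azimuth, .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "azimuth (rad, TM1 at 0)", y = what) +
    ggplot2::theme_minimal()
  if (!is.null(marks)) {
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$azimuth),
                                 linetype = "dashed", alpha = 0.4)
  }
  p
}

#' Plot the monomer count time series
#'
#' @param counts Result of [count_monomers()] (optionally several bound
#'   together with a `replica` column).
#' @return A ggplot line of monomers versus time.
#' @export
plot_monomer_counts <- function(counts) {
  p <- ggplot2::ggplot(counts, ggplot2::aes(.data$time, .data$n_monomers))
  if ("replica" %in% names(counts)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$replica),
                                alpha = 0.4) +
      ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1)
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "time (ns)", y = "monomeric receptors") +
    ggplot2::theme_minimal()
}
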