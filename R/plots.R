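#' @importFrom ggplot2 autoplot
NULL

#' Plot a curvature tuning curve
#'
#' Normalized response against arc radius, with the 90%-of-maximum band
#' shaded.
#'
#' @param object An `sc_tuning` tibble from [curvature_tuning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sc_tuning
#' @export
autoplot.sc_tuning <- function(object, ...) {
  band <- attr(object, "band")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$radius,
                                    y = .data$response_norm)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = 0.9, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "arc radius (px)", y = "normalized response",
                  title = paste0("Degree-of-curvature tuning, scale ",
                                 attr(object, "scale"))) +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[["low"]],
                               xmax = band[["high"]], ymin = -Inf,
                               ymax = Inf, alpha = 0.12, fill = "steelblue")
  }
  p
}

#' Plot a stimulus image
#'
#' @param object A [stimulus_image()].
#' @param ... Unused.
#' @return A ggplot raster of the contour.
#' @method autoplot stimulus_image
#' @export
autoplot.stimulus_image <- function(object, ...) {
  px <- pixel_coords(object)
  ggplot2::ggplot(px, ggplot2::aes(x = .data$x, y = .data$y,
                                   alpha = .data$value)) +
    ggplot2::geom_raster(fill = "white") +
    ggplot2::scale_y_reverse(limits = c(nrow(object) - 1, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, ncol(object) - 1)) +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(panel.background =
                     ggplot2::element_rect(fill = "black"))
}

#' Plot a signed local-curvature map
#'
#' One panel per signed curvature class, plus the straight-flagged
#' locations.
#'
#' @param object A [curvature_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curvature_map
#' @export
autoplot.curvature_map <- function(object, ...) {
  recs <- tidy(object)
  recs$panel <- paste0("scale ", recs$scale, ", ", recs$sign)
  st <- straight_pixels(object)
  if (nrow(st) > 0) {
    st$value <- 1
    st$panel <- "straight"
    recs <- dplyr::bind_rows(recs, st)
  }
  ggplot2::ggplot(recs, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "response") +
    ggplot2::theme_minimal()
}

#' Plot a shape-neuron response profile
#'
#' @param object An `sc_profile` from [response_profile()].
#' @param top Show only the strongest `top` stimuli (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sc_profile
#' @export
autoplot.sc_profile <- function(object, top = NULL, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object),
                       dplyr::desc(.data$response))
  if (!is.null(top)) df <- utils::head(df, top)
  df$id <- factor(df$id, levels = rev(df$id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$id)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "normalized response", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model-vs-reference comparison report
#'
#' @param object An `sc_comparison` from [comparison_report()].
#' @param ... Unused.
#' @return A ggplot bar chart of per-neuron mean absolute differences.
#' @method autoplot sc_comparison
#' @export
autoplot.sc_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neuron,
                                   y = .data$mean_abs_diff)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$mean_abs_diff - .data$stdev),
      ymax = .data$mean_abs_diff + .data$stdev), width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean |model - reference|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
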