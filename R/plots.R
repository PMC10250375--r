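#' Tile plot of a growth-temperature correlation grid
#'
#' Draws the upper-triangular pair grid with tiles coloured by Pearson r;
#' non-significant tiles are dimmed so the adjacent significant patches the
#' sensitivity rule looks for stand out.
#'
#' @param object A `correlation_grid`.
#' @param alpha Significance level used for dimming.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_grid <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      significant = .data$p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_pos, y = .data$end_pos)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r, alpha = .data$significant)) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "start position in selection range",
                  y = "end position in selection range",
                  fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Climate-space plot of boundary lines and observations
#'
#' @param object A `boundary_model`.
#' @param P0 Thresholds at which to draw boundary lines.
#' @param observations Optional (MAT, MAP, group) table to overlay.
#' @param mat_range MAT range (degC) over which to draw the lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boundary_model <- function(object, P0 = c(0.5, 0.75, 0.95),
                                    observations = NULL,
                                    mat_range = c(-15, 5), ...) {
  b <- climate_boundary(object, P0)
  p <- ggplot2::ggplot()
  if (!is.null(observations)) {
    p <- p + ggplot2::geom_point(
      data = observations,
      ggplot2::aes(x = .data$MAT, y = .data$MAP, colour = .data$group),
      alpha = 0.5) +
      ggplot2::scale_colour_manual(values = c(negative = "#B2182B",
                                              positive = "#2166AC"))
  }
  p + ggplot2::geom_abline(
    data = b, ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                           linetype = factor(.data$P0))) +
    ggplot2::coord_cartesian(xlim = mat_range) +
    ggplot2::labs(x = "MAT (degC)", y = "MAP (mm)", linetype = "P0") +
    ggplot2::theme_minimal()
}

#' Map plot of classified response regions
#'
#' @param object A `response_region_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_region_map <- function(object, ...) {
  m <- object$labels
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$label <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      negative = "#B2182B", positive = "#2166AC",
      outside_climate_space = "grey55", non_habitat = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = sprintf("Response regions (P0 = %.2f)", object$P0)) +
    ggplot2::theme_void()
}
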