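#' Plot cell positions colored by type
#'
#' Simple x-y diagnostic map of a tissue's cell centroids with FOV grid
#' lines.
#'
#' @param sample An annotated `tissue_sample`.
#' @return A ggplot object.
#' @export
plot_tissue <- function(sample) {
  df <- sample$cells
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$type_label)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "cell type",
                  title = sample$tissue_id) +
    ggplot2::theme_minimal()
}

#' Quiver-style plot of current and predicted future cell states
#'
#' Draws each cell at its current PC1-PC2 position with a segment to its
#' projected future position, optionally colored by a per-cell covariate
#' such as the minimum distance to another cell type.
#'
#' @param future A result list from [compute_future_states()].
#' @param colour_by Optional numeric vector (one value per cell).
#' @return A ggplot object.
#' @export
plot_state_change <- function(future, colour_by = NULL) {
  df <- tibble::tibble(
    x = future$scores_current[, 1], y = future$scores_current[, 2],
    xend = future$scores_future[, 1], yend = future$scores_future[, 2])
  if (!is.null(colour_by)) df$colour_by <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (is.null(colour_by)) {
    p + ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      alpha = 0.6)
  } else {
    p + ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$yend,
                   colour = .data$colour_by),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      alpha = 0.8) +
      ggplot2::scale_colour_viridis_c(name = "distance (µm)")
  }
  p + ggplot2::labs(x = "PC1", y = "PC2") + ggplot2::theme_minimal()
}

#' Expression-versus-distance scatter with the fitted line
#'
#' @param expression,distances Per-cell vectors for one gene and pair.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_distance_response <- function(expression, distances, title = NULL) {
  df <- tibble::tibble(distance = distances, expression = expression)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance,
                                   y = .data$expression)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "minimum distance (µm)", y = "counts",
                  title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pc_embedding <- function(object, ...) {
  df <- tibble::tibble(PC1 = object$scores[, 1],
                       PC2 = if (ncol(object$scores) > 1)
                         object$scores[, 2] else 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$explained[1]),
      y = if (length(object$explained) > 1)
        sprintf("PC2 (%.0f%%)", 100 * object$explained[2]) else "PC2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
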