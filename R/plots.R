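#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Phase-plane plot of the stationary states
#'
#' Draws the three stationary states in the (p50, p65) protein plane,
#' optionally overlaying a quasi-potential landscape or a trajectory.
#'
#' @param object A `stability_report`.
#' @param landscape Optional `grn_landscape` drawn underneath.
#' @param trajectory Optional `grn_trajectory` drawn as a path.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, landscape = NULL,
                                      trajectory = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(landscape)) {
    p <- p + ggplot2::geom_raster(
      data = landscape,
      ggplot2::aes(x = .data$p50, y = .data$p65, fill = .data$potential)) +
      ggplot2::scale_fill_viridis_c(direction = -1)
  }
  if (!is.null(trajectory)) {
    p <- p + ggplot2::geom_path(
      data = trajectory,
      ggplot2::aes(x = .data$P_p50, y = .data$P_p65),
      alpha = 0.5, colour = "#6a3d9a")
  }
  p + ggplot2::geom_point(
    data = object$states,
    ggplot2::aes(x = .data$P_p50, y = .data$P_p65,
                 shape = .data$classification),
    size = 3, colour = "black", fill = "white") +
    ggplot2::scale_shape_manual(values = c(stable = 19, saddle = 21,
                                           unstable = 4)) +
    ggplot2::labs(x = "p50 protein (molecules)",
                  y = "p65 protein (molecules)", shape = "state")
}
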