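# ggplot2 views of the package's result objects.

#' Plot a toolpath
#'
#' Top view of the waypoints, coloured by layer, sized by extruded volume.
#'
#' @param x A [toolpath()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_toolpath <- function(x, ...) {
  stopifnot(inherits(x, "toolpath"))
  df <- tibble::as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = factor(.data$layer))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(size = .data$extrude), alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", colour = "layer",
                  size = "extrude [ul]",
                  title = sprintf("%s toolpath, %.2f ul",
                                  attr(x, "strategy"),
                                  attr(x, "total_volume_ul"))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_toolpath
#' @export
autoplot.toolpath <- function(x, ...) plot_toolpath(x, ...)

#' Plot a tracking trace
#'
#' Tracking error over time, corner-labelled steps highlighted.
#'
#' @param x A `tracking_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_tracking_trace <- function(x, ...) {
  stopifnot(inherits(x, "tracking_trace"))
  df <- tibble::as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$error_mm,
                                   colour = .data$segment)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "t [s]", y = "tracking error [mm]",
                  title = sprintf("%s trajectory at %.0f mm/s",
                                  attr(x, "kind"), attr(x, "speed"))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_tracking_trace
#' @export
autoplot.tracking_trace <- function(x, ...) plot_tracking_trace(x, ...)

#' Plot a workspace estimate
#'
#' Occupied voxels in the chosen projection plane, shaded by hit count.
#'
#' @param x A `workspace_estimate`.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_workspace <- function(x, plane = c("xz", "xy", "yz"), ...) {
  stopifnot(inherits(x, "workspace_estimate"))
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  df <- x$voxels
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                   fill = .data$hits)) +
    ggplot2::geom_tile(width = x$voxel_size, height = x$voxel_size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(ax[1], " [mm]"), y = paste0(ax[2], " [mm]"),
                  title = sprintf("workspace: %.3g mm^3 (%d voxels)",
                                  x$volume_mm3, nrow(x$voxels))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_workspace
#' @export
autoplot.workspace_estimate <- function(x, ...) plot_workspace(x, ...)

#' @export
autoplot <- function(x, ...) UseMethod("autoplot")
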