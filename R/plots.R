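# ggplot2 visualisations for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scalar map
#'
#' @param object a [map_matrix].
#' @param ... unused.
#' @return a ggplot raster with invalid pixels blank.
#' @export
autoplot.map_matrix <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d[d$valid, ], ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot an orientation field
#'
#' Angle is colour-coded over the axial range 0-180 degrees.
#' @param object an [orientation_field].
#' @param ... unused.
#' @return a ggplot raster.
#' @export
autoplot.orientation_field <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[d$valid, ]
  d$angle_deg <- d$theta * 180 / pi
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$angle_deg)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(
      colours = c("#d73027", "#fee090", "#1a9850", "#4575b4", "#d73027"),
      limits = c(0, 180), name = "axis (deg)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Quiver plot of a conduction vector field
#'
#' @param object a [vector_field].
#' @param stride sample every `stride`-th pixel.
#' @param scale arrow length per mm/ms, in px.
#' @param ... unused.
#' @return a ggplot with arrows along the local propagation direction.
#' @export
autoplot.vector_field <- function(object, stride = 8, scale = 10, ...) {
  d <- as_tibble(object)
  d <- d[d$valid & (d$x %% stride == 0) & (d$y %% stride == 0), ]
  d$xend <- d$x + scale * d$speed * cos(d$angle)
  d$yend <- d$y + scale * d$speed * sin(d$angle)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                  yend = .data$yend, colour = .data$speed)) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "mm/ms") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a tissue activation curve
#'
#' @param object an `activation_curve` tibble.
#' @param ... unused.
#' @return a ggplot step curve of cumulative activated fraction.
#' @export
autoplot.activation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$fraction_activated)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ms)", y = "fraction activated") +
    ggplot2::theme_minimal()
}

#' Plot a traced fiber graph coloured by size bin
#'
#' @param object a `fiber_graph`.
#' @param ... unused.
#' @return a ggplot of segment paths coloured by diameter bin.
#' @export
autoplot.fiber_graph <- function(object, ...) {
  segs <- fiber_segments(object)
  if (nrow(segs) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  pts <- dplyr::bind_rows(lapply(seq_len(nrow(segs)), function(i) {
    idx <- match(segs$path[[i]], object$nodes$node)
    tibble::tibble(segment = i, bin = segs$bin[i],
                   x = object$nodes$x[idx], y = object$nodes$y[idx])
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y, group = .data$segment,
                                    colour = .data$bin)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "size bin") +
    ggplot2::theme_minimal()
}

#' Scatter plot of the anisotropy vs activation-time composite
#'
#' @param composite result of [bz_composite()].
#' @return a ggplot scatter with BZ points highlighted.
#' @export
plot_composite <- function(composite) {
  d <- composite$data
  ggplot2::ggplot(d, ggplot2::aes(.data$anisotropy_index,
                                  .data$tissue_activation_time)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_bz, shape = .data$group),
                        size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "magenta"),
                                 name = "border zone") +
    ggplot2::labs(x = "anisotropy index (1/mm^2)",
                  y = "tissue activation time (ms/mm)") +
    ggplot2::theme_minimal()
}
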