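# autoplot() methods for the package's result types (ggplot2).

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an information-plane trajectory
#'
#' Predictive information versus total utilized information along the
#' annealed sweep; optionally overlays an exact subset frontier.
#'
#' @param object A `dib_info_plane`.
#' @param frontier Optional `dib_frontier` to overlay as discrete points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dib_info_plane
#' @export
autoplot.dib_info_plane <- function(object, frontier = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$total_bits,
                                    y = .data$predictive_bits))
  if (!is.null(frontier)) {
    fr <- tibble::tibble(size = frontier$size, mi_bits = frontier$mi_bits)
    p <- p + ggplot2::geom_point(
      data = fr, ggplot2::aes(x = .data$size, y = .data$mi_bits),
      colour = "black", alpha = 0.4, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = log10(.data$beta)), size = 1.6) +
    ggplot2::scale_colour_viridis_c(name = expression(log[10] ~ beta)) +
    ggplot2::labs(x = "total utilized information (bits)",
                  y = "predictive information (bits)") +
    ggplot2::theme_minimal()
}

#' Plot an information-allocation heatmap
#'
#' @param object A `dib_allocation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dib_allocation
#' @export
autoplot.dib_allocation <- function(object, ...) {
  feats <- attr(object, "features")
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(round(.data$total_bits, 2),
               levels = unique(round(sort(.data$total_bits), 2))),
    y = factor(.data$feature, levels = rev(feats)),
    fill = .data$bits)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "bits") +
    ggplot2::labs(x = "total utilized information (bits)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a distinguishability matrix
#'
#' @param object A `dib_distinguishability`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dib_distinguishability
#' @export
autoplot.dib_distinguishability <- function(object, ...) {
  grid <- attr(object, "grid")
  df <- expand.grid(i = seq_along(grid), j = seq_along(grid))
  df$value <- as.vector(unclass(object))
  df$xa <- grid[df$i]
  df$xb <- grid[df$j]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$xa, y = .data$xb,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "distinguishability",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = attr(object, "feature"), y = attr(object, "feature")) +
    ggplot2::theme_minimal()
}

#' Plot class-conditional histograms
#'
#' @param object A `dib_cond_hist`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dib_cond_hist
#' @export
autoplot.dib_cond_hist <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("density_0", "density_1"),
                              names_to = "class", values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$density,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::labs(x = attr(object, "feature"), y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a radial distribution function
#'
#' @param object A `dib_rdf`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dib_rdf
#' @export
autoplot.dib_rdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (simulation units)",
                  y = sprintf("g[%s](r)", object$pair[1])) +
    ggplot2::theme_minimal()
}

#' Plot a positional information map
#'
#' @param object A `dib_posmap`.
#' @param which `"cells"` for the 2D map, `"radial"` for the annulus
#'   average.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dib_posmap
#' @export
autoplot.dib_posmap <- function(object, which = c("cells", "radial"), ...) {
  which <- match.arg(which)
  if (which == "cells") {
    ggplot2::ggplot(object$cells,
                    ggplot2::aes(x = .data$x, y = .data$y,
                                 fill = .data$bits)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~type) +
      ggplot2::coord_equal() +
      ggplot2::scale_fill_viridis_c(name = "bits / particle") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$radial,
                    ggplot2::aes(x = .data$r, y = .data$bits,
                                 colour = .data$type)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "r (simulation units)", y = "bits / particle") +
      ggplot2::theme_minimal()
  }
}

#' Plot a positional distinguishability field
#'
#' @param object A `dib_posfield`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dib_posfield
#' @export
autoplot.dib_posfield <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$distinguishability)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal()
}
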