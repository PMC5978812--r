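#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tissue network
#'
#' Draws the cell polygons of a monolayer, optionally filled by a per-cell
#' quantity (effective pressure by default when parameters are supplied,
#' reproducing the familiar dark-tension / light-compression maps).
#'
#' @param object A [tissue_network()].
#' @param params Optional [model_params()]; enables mechanical fills.
#' @param fill Per-cell fill: one of `"p_eff"`, `"z"`, `"area"`,
#'   `"circularity"`, `"none"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_network <- function(object, params = NULL,
                                    fill = c("p_eff", "z", "area",
                                             "circularity", "none"), ...) {
  fill <- match.arg(fill)
  if (fill == "p_eff" && is.null(params)) fill <- "none"
  tab <- if (!is.null(params)) cell_table(object, params) else
    network_geometry(object)
  s <- object$slots
  x <- slot_coords(object$vertices, s, object$box)
  df <- tibble::tibble(
    cell = s$cell,
    px = x[, 1], py = x[, 2]
  )
  if (fill != "none") {
    df$fill_val <- tab[[switch(fill, p_eff = "p_eff", z = "z",
                               area = "area", circularity = "circularity")]][s$cell]
  }
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py, group = .data$cell))
  gg <- if (fill == "none") {
    gg + ggplot2::geom_polygon(fill = "grey90", colour = "grey30",
                               linewidth = 0.3)
  } else {
    gg + ggplot2::geom_polygon(ggplot2::aes(fill = .data$fill_val),
                               colour = "grey20", linewidth = 0.25) +
      ggplot2::scale_fill_viridis_c(name = fill)
  }
  gg + ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a likelihood surface
#'
#' Heat map of the grid log-likelihood with the argmax marked.
#'
#' @param object A [grid_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vertex_fit <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$lam, .data$gam, fill = .data$loglik)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$argmax, colour = "white", size = 3,
                        shape = 21, stroke = 1.2) +
    ggplot2::scale_fill_viridis_c(name = "log-likelihood") +
    ggplot2::labs(x = expression(Lambda), y = expression(Gamma)) +
    ggplot2::theme_minimal()
}

#' Plot class summaries
#'
#' Mean normalized area (or circularity) per polygonal class, optionally
#' comparing simulation against an observed table.
#'
#' @param object A [class_summary()] tibble.
#' @param compare Optional second `class_summary` (drawn as points).
#' @param quantity `"mean_norm_area"` or `"mean_circularity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_summary <- function(object, compare = NULL,
                                   quantity = c("mean_norm_area",
                                                "mean_circularity"), ...) {
  quantity <- match.arg(quantity)
  gg <- ggplot2::ggplot(object,
                        ggplot2::aes(.data$class, .data[[quantity]])) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::labs(x = "polygonal class", y = quantity) +
    ggplot2::theme_minimal()
  if (!is.null(compare)) {
    gg <- gg + ggplot2::geom_point(data = compare, size = 3,
                                   colour = "black")
  }
  gg
}

#' Parameter-space map
#'
#' The (Lambda, Gamma) plane partitioned into the soft (I), single-
#' equilibrium (IIa), bistable (IIb) and collapse (III) regions, with
#' optional points overlaid.
#'
#' @param lam_range,gam_range Plot limits.
#' @param points Optional tibble with `lam`, `gam` columns to overlay.
#' @param n Grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_parameter_space <- function(lam_range = c(-1.5, 0.5),
                                 gam_range = c(0.01, 0.3),
                                 points = NULL, n = 201) {
  grid <- tidyr_expand_grid(
    lam = seq(lam_range[1], lam_range[2], length.out = n),
    gam = seq(gam_range[1], gam_range[2], length.out = n)
  )
  grid$region <- vapply(seq_len(nrow(grid)), function(i) {
    classify_region_label(grid$lam[i], grid$gam[i])
  }, character(1))
  gg <- ggplot2::ggplot(grid, ggplot2::aes(.data$lam, .data$gam,
                                           fill = .data$region)) +
    ggplot2::geom_raster(alpha = 0.7) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "region") +
    ggplot2::labs(x = expression(Lambda), y = expression(Gamma)) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    gg <- gg + ggplot2::geom_point(data = points, inherit.aes = FALSE,
                                   ggplot2::aes(.data$lam, .data$gam))
  }
  gg
}
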