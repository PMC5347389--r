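#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_ribbon
#'   geom_segment geom_polygon labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a fitted concentration-response curve
#'
#' @param object A `crc_fit`.
#' @param n_grid Points along the concentration axis.
#' @param ... Unused.
#' @return A ggplot: observed points, fitted curve and 95% confidence band
#'   on a log concentration axis.
#' @export
autoplot.crc_fit <- function(object, n_grid = 200L, ...) {
  rng <- range(object$data$concentration)
  grid <- 10^seq(lg(rng[1L]), lg(rng[2L]), length.out = n_grid)
  curve <- predict(object, grid, interval = "confidence")
  ggplot(curve, aes(x = .data$concentration, y = .data$effect)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                fill = "grey80", alpha = 0.6) +
    geom_line(colour = "steelblue") +
    geom_point(data = object$data) +
    ggplot2::scale_x_log10() +
    labs(x = "concentration (mol/L)", y = "effect (%)",
         title = sprintf("%s fit (R² = %.4f)", object$family,
                         object$r_squared)) +
    theme_minimal()
}

#' Plot the triangulation and tessellation of an interpolation model
#'
#' @param object A `mix_interpolator`.
#' @param show One or both of `"delaunay"`, `"voronoi"`.
#' @param ... Unused.
#' @return A ggplot of the training vertices with triangulation edges
#'   and/or Voronoi cell boundaries in the interpolation coordinate space.
#' @export
autoplot.mix_interpolator <- function(object,
                                      show = c("delaunay", "voronoi"), ...) {
  show <- match.arg(show, several.ok = TRUE)
  pts <- tibble::tibble(x = object$delaunay$points[, 1L],
                        y = object$delaunay$points[, 2L],
                        effect = object$values)
  gg <- ggplot(pts, aes(x = .data$x, y = .data$y))
  if ("voronoi" %in% show) {
    polys <- voronoi_polygons(object$voronoi)
    gg <- gg + geom_polygon(data = polys,
                            aes(group = .data$cell),
                            fill = NA, colour = "grey70", linewidth = 0.3)
  }
  if ("delaunay" %in% show) {
    edges <- delaunay_edges(object$delaunay)
    gg <- gg + geom_segment(data = edges,
                            aes(x = .data$x0, y = .data$y0,
                                xend = .data$x1, yend = .data$y1),
                            colour = "grey40", linewidth = 0.3)
  }
  axis_lab <- if (object$coordinate_space == "log10") {
    c("lg concentration A", "lg concentration B")
  } else {
    c("concentration A (mol/L)", "concentration B (mol/L)")
  }
  rng_x <- range(pts$x); rng_y <- range(pts$y)
  pad <- 0.05
  gg + geom_point(aes(colour = .data$effect), size = 1.5) +
    ggplot2::scale_colour_viridis_c(name = "effect (%)") +
    ggplot2::coord_cartesian(
      xlim = rng_x + pad * diff(rng_x) * c(-1, 1),
      ylim = rng_y + pad * diff(rng_y) * c(-1, 1)) +
    labs(x = axis_lab[1L], y = axis_lab[2L]) +
    theme_minimal()
}

#' Plot cross-validation residuals against observations
#'
#' @param object A `mix_validation`.
#' @param ... Unused.
#' @return A ggplot of predicted vs observed effects per method.
#' @export
autoplot.mix_validation <- function(object, ...) {
  pp <- object$per_point |>
    tidyr::pivot_longer(dplyr::any_of(c("pred_linip", "pred_neiip")),
                        names_to = "method", names_prefix = "pred_",
                        values_to = "pred") |>
    dplyr::filter(is.finite(.data$pred))
  ggplot(pp, aes(x = .data$effect, y = .data$pred)) +
    geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "steelblue") +
    ggplot2::facet_wrap(~method) +
    labs(x = "observed effect (%)", y = "predicted effect (%)",
         title = sprintf("%s predictions", object$scheme)) +
    theme_minimal()
}
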