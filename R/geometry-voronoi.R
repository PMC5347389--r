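# Voronoi tessellation and Sibson natural-neighbour weights.
#
# Each Voronoi cell is computed directly as the intersection of bisector
# half-planes with a clipping box, by Sutherland-Hodgman clipping of a
# convex polygon. Unbounded cells are clipped to the data bounding box
# expanded by a multiple of its diagonal; Sibson weights are ratios of
# stolen areas, so hull-interior queries are insensitive to the margin.

# clip convex polygon (m x 2, counter-clockwise) to the half-plane
# {x : a . x <= b}; returns the clipped polygon or NULL when empty
clip_halfplane <- function(poly, a, b, tol = 1e-13) {
  s <- poly[, 1L] * a[1L] + poly[, 2L] * a[2L] - b
  if (all(s <= tol)) return(poly)
  if (all(s >= -tol)) return(NULL)
  m <- nrow(poly)
  out <- matrix(NA_real_, m + 4L, 2L)
  k <- 0L
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    si <- s[i]; sj <- s[j]
    if (si <= tol) {
      k <- k + 1L
      out[k, ] <- poly[i, ]
    }
    if ((si < -tol && sj > tol) || (si > tol && sj < -tol)) {
      t <- si / (si - sj)
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (k < 3L) return(NULL)
  out[seq_len(k), , drop = FALSE]
}

polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# cell of site i: clip the box by the bisector against every other site,
# nearest first, stopping once remaining sites are too far to cut
voronoi_cell <- function(pts, i, box) {
  pi_ <- pts[i, ]
  d2 <- (pts[, 1L] - pi_[1L])^2 + (pts[, 2L] - pi_[2L])^2
  ord <- order(d2)
  ord <- ord[ord != i]
  poly <- box
  for (j in ord) {
    r2 <- max((poly[, 1L] - pi_[1L])^2 + (poly[, 2L] - pi_[2L])^2)
    if (d2[j] > 4 * r2) break
    a <- pts[j, ] - pi_
    b <- (sum(pts[j, ]^2) - sum(pi_^2)) / 2
    poly <- clip_halfplane(poly, a, b)
    if (is.null(poly)) {
      abort("empty Voronoi cell; duplicate points?",
            class = "mixray_geometry_error")
    }
  }
  poly
}

#' Voronoi tessellation of training vertices
#'
#' Computes the Voronoi cell of every point (the region of the plane
#' nearer to it than to any other point), clipped to the data bounding box
#' expanded by `expand` times its diagonal. The tessellation is the
#' geometric dual of the Delaunay triangulation.
#'
#' @param xy Two-column numeric matrix of point coordinates (>= 3
#'   non-collinear points, no duplicates).
#' @param expand Clipping-box margin as a multiple of the bounding-box
#'   diagonal (default 3).
#' @return An object of class `voronoi`: `points`, `cells` (list of
#'   polygon matrices), `areas`, the clipping `box`, and the dual
#'   `delaunay` (used for convex-hull tests).
#' @export
build_voronoi <- function(xy, expand = 3) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  dt <- build_delaunay(xy) # validates input, supplies hull tests
  # uniform rescale for conditioning: preserves the tessellation and all
  # area ratios, and makes the absolute clipping tolerances meaningful
  ctr <- colMeans(xy)
  scale <- max(apply(xy, 2L, function(v) diff(range(v))), .Machine$double.eps)
  pts <- sweep(xy, 2L, ctr) / scale
  rng_x <- range(pts[, 1L]); rng_y <- range(pts[, 2L])
  diag_len <- sqrt(diff(rng_x)^2 + diff(rng_y)^2)
  m <- expand * diag_len
  box <- rbind(c(rng_x[1L] - m, rng_y[1L] - m),
               c(rng_x[2L] + m, rng_y[1L] - m),
               c(rng_x[2L] + m, rng_y[2L] + m),
               c(rng_x[1L] - m, rng_y[2L] + m))
  cells <- lapply(seq_len(nrow(pts)), function(i) voronoi_cell(pts, i, box))
  structure(
    list(points = xy, scaled = pts, ctr = ctr, scale = scale,
         cells = cells,
         areas = vapply(cells, polygon_area, numeric(1L)),
         box = box, delaunay = dt),
    class = "voronoi")
}

#' @export
print.voronoi <- function(x, ...) {
  cat(sprintf("<voronoi> %d cells\n", length(x$cells)))
  invisible(x)
}

#' Sibson natural-neighbour weights of a query point
#'
#' Inserting a query point q into the tessellation creates a new cell V(q)
#' that steals area from the cells of its natural neighbours; the Sibson
#' weight of neighbour i is the stolen area Area(V_i intersect V(q))
#' divided by Area(V(q)). Weights are non-negative and sum to 1. A query
#' coinciding with a training vertex gets weight 1 on that vertex; queries
#' outside the convex hull are refused.
#'
#' @param vor A [build_voronoi()] object.
#' @param q Query point, length-2 numeric.
#' @return A tibble with `index` (training point index) and `weight`, or
#'   `NULL` when q lies outside the convex hull.
#' @export
sibson_weights <- function(vor, q) {
  pts <- vor$scaled
  qs <- (q - vor$ctr) / vor$scale
  d2 <- (pts[, 1L] - qs[1L])^2 + (pts[, 2L] - qs[2L])^2
  hit <- which(d2 <= 1e-24)
  if (length(hit)) {
    return(tibble::tibble(index = hit[1L], weight = 1))
  }
  if (is.null(tri_locate(vor$delaunay, q))) return(NULL)
  stolen <- numeric(nrow(pts))
  for (i in order(d2)) {
    cell <- vor$cells[[i]]
    # half-plane of points nearer to q than to site i
    a <- pts[i, ] - qs
    b <- (sum(pts[i, ]^2) - sum(qs^2)) / 2
    piece <- clip_halfplane(cell, a, b)
    stolen[i] <- polygon_area(piece)
  }
  nb <- which(stolen > 0)
  tibble::tibble(index = nb, weight = stolen[nb] / sum(stolen[nb]))
}

#' Natural-neighbour (Sibson) interpolation
#'
#' `f(q) = sum_i W_i f(x_i)` over the natural neighbours of q, with W the
#' Sibson stolen-area weights.
#'
#' @param vor A [build_voronoi()] object.
#' @param q Query coordinates: length-2 vector or 2-column matrix.
#' @param values Vertex values, same order as the points.
#' @return Numeric vector of interpolated values; `NA` outside the hull.
#' @export
natural_neighbor_interpolate <- function(vor, q, values) {
  qm <- if (is.null(dim(q))) matrix(q, ncol = 2L) else as.matrix(q)
  vapply(seq_len(nrow(qm)), function(k) {
    w <- sibson_weights(vor, qm[k, ])
    if (is.null(w)) return(NA_real_)
    sum(w$weight * values[w$index])
  }, numeric(1L))
}

#' Voronoi cell polygons as a tidy table (for plotting or export)
#'
#' @param vor A [build_voronoi()] object.
#' @return A tibble with one row per polygon vertex: `cell`, `vertex`,
#'   `x`, `y`.
#' @export
voronoi_polygons <- function(vor) {
  purrr::map_dfr(seq_along(vor$cells), function(i) {
    p <- vor$cells[[i]]
    tibble::tibble(cell = i, vertex = seq_len(nrow(p)),
                   x = p[, 1L] * vor$scale + vor$ctr[1L],
                   y = p[, 2L] * vor$scale + vor$ctr[2L])
  })
}
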