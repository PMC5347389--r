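# Delaunay triangulation of scattered points in the concentration plane.
#
# Bowyer-Watson incremental insertion with cached circumcircles. Sizes here
# are small (the canonical training set has 84 vertices), so each insertion
# scans all current triangles with vectorised in-circumcircle tests.
# On-circle ties (|d^2 - r^2| below tolerance) are treated as "not inside",
# which keeps the triangulation valid and makes the output deterministic
# for a given input order.

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2
  b2 <- bx^2 + by^2
  c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ux - ax)^2 + (uy - ay)^2, degenerate = abs(d) < 1e-14)
}

#' Delaunay triangulation of training vertices
#'
#' Builds the Delaunay triangulation of a set of 2-D points by incremental
#' insertion. Every triangle satisfies the empty-circumcircle property (to
#' numerical tolerance); triangles are non-overlapping and cover the convex
#' hull of the points.
#'
#' @param xy Two-column numeric matrix (or data frame) of point
#'   coordinates; at least 3 non-collinear points, no duplicates.
#' @return An object of class `delaunay`: `points` (the input matrix),
#'   `triangles` (integer matrix, one row per triangle, vertex indices
#'   sorted within and across rows), and cached barycentric transforms for
#'   point location.
#' @export
build_delaunay <- function(xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (n < 3L) abort("need at least 3 points.", class = "mixray_geometry_error")
  if (anyDuplicated(xy)) {
    abort("duplicate points in the training set.", class = "mixray_geometry_error")
  }

  # uniform rescale for conditioning (preserves the triangulation)
  ctr <- colMeans(xy)
  scale <- max(apply(xy, 2L, function(v) diff(range(v))), .Machine$double.eps)
  pts <- sweep(xy, 2L, ctr) / scale

  # super-triangle far outside the data
  m <- 64
  sv <- rbind(c(0, m), c(-m, -m), c(m, -m))
  all_pts <- rbind(pts, sv)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tri <- matrix(c(s1, s2, s3), ncol = 3L)
  cc <- circumcircle(sv[1, 1], sv[1, 2], sv[2, 1], sv[2, 2], sv[3, 1], sv[3, 2])
  ccx <- cc$x; ccy <- cc$y; ccr <- cc$r2

  eps <- 1e-12
  for (i in seq_len(n)) {
    px <- all_pts[i, 1L]; py <- all_pts[i, 2L]
    d2 <- (px - ccx)^2 + (py - ccy)^2
    bad <- which(d2 < ccr * (1 - eps) - eps)
    if (!length(bad)) {
      abort("point fell outside all circumcircles; degenerate configuration.",
            class = "mixray_geometry_error")
    }
    # boundary of the cavity: edges of bad triangles appearing exactly once
    bt <- tri[bad, , drop = FALSE]
    e <- rbind(bt[, c(1L, 2L)], bt[, c(2L, 3L)], bt[, c(1L, 3L)])
    key <- pmin(e[, 1L], e[, 2L]) * (n + 4) + pmax(e[, 1L], e[, 2L])
    once <- !(key %in% key[duplicated(key)])
    boundary <- e[once, , drop = FALSE]

    keep <- setdiff(seq_len(nrow(tri)), bad)
    tri <- tri[keep, , drop = FALSE]
    ccx <- ccx[keep]; ccy <- ccy[keep]; ccr <- ccr[keep]

    new_tri <- cbind(boundary, i)
    ncc <- circumcircle(all_pts[new_tri[, 1L], 1L], all_pts[new_tri[, 1L], 2L],
                        all_pts[new_tri[, 2L], 1L], all_pts[new_tri[, 2L], 2L],
                        all_pts[new_tri[, 3L], 1L], all_pts[new_tri[, 3L], 2L])
    if (any(ncc$degenerate)) {
      abort("degenerate (collinear) triangle during insertion.",
            class = "mixray_geometry_error")
    }
    tri <- rbind(tri, new_tri)
    ccx <- c(ccx, ncc$x); ccy <- c(ccy, ncc$y); ccr <- c(ccr, ncc$r2)
  }

  real <- tri[, 1L] <= n & tri[, 2L] <= n & tri[, 3L] <= n
  tri <- tri[real, , drop = FALSE]
  if (!nrow(tri)) {
    abort("all points are collinear; no triangulation exists.",
          class = "mixray_geometry_error")
  }
  tri <- t(apply(tri, 1L, sort))
  tri <- tri[order(tri[, 1L], tri[, 2L], tri[, 3L]), , drop = FALSE]
  dimnames(tri) <- NULL

  structure(
    list(points = xy, triangles = tri, bary = bary_cache(xy, tri)),
    class = "delaunay")
}

# cached affine transforms for vectorised barycentric point location
bary_cache <- function(xy, tri) {
  x1 <- xy[tri[, 1L], 1L]; y1 <- xy[tri[, 1L], 2L]
  x2 <- xy[tri[, 2L], 1L]; y2 <- xy[tri[, 2L], 2L]
  x3 <- xy[tri[, 3L], 1L]; y3 <- xy[tri[, 3L], 2L]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, x3 = x3, y3 = y3, det = det)
}

# locate the triangle containing q; returns list(tri = index, l = barycentric)
# or NULL when q is outside the convex hull. tol is relative slack on the
# barycentric coordinates so hull-edge queries are accepted.
tri_locate <- function(dt, q, tol = 1e-9) {
  b <- dt$bary
  l1 <- ((b$y2 - b$y3) * (q[1L] - b$x3) + (b$x3 - b$x2) * (q[2L] - b$y3)) / b$det
  l2 <- ((b$y3 - b$y1) * (q[1L] - b$x3) + (b$x1 - b$x3) * (q[2L] - b$y3)) / b$det
  l3 <- 1 - l1 - l2
  ok <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
  if (!length(ok)) return(NULL)
  i <- ok[1L]
  list(tri = i, l = c(l1[i], l2[i], l3[i]))
}

#' Linear interpolation on a Delaunay triangulation
#'
#' Locates the triangle containing each query point and evaluates the plane
#' `Z = aX + bY + c` through its three vertices, with the coefficients
#' obtained by solving the 3x3 linear system of the vertex coordinates.
#' Queries outside the convex hull are never extrapolated.
#'
#' @param dt A [build_delaunay()] object.
#' @param q Query coordinates: a length-2 vector or a 2-column matrix.
#' @param values Numeric vector of vertex values (same order as the points).
#' @return Numeric vector of interpolated values; `NA` marks queries
#'   outside the convex hull.
#' @export
linear_interpolate <- function(dt, q, values) {
  qm <- if (is.null(dim(q))) matrix(q, ncol = 2L) else as.matrix(q)
  vapply(seq_len(nrow(qm)), function(k) {
    loc <- tri_locate(dt, qm[k, ])
    if (is.null(loc)) return(NA_real_)
    v <- dt$triangles[loc$tri, ]
    A <- cbind(dt$points[v, , drop = FALSE], 1)
    abc <- solve(A, values[v])
    sum(abc * c(qm[k, ], 1))
  }, numeric(1L))
}

#' @export
print.delaunay <- function(x, ...) {
  cat(sprintf("<delaunay> %d points, %d triangles\n",
              nrow(x$points), nrow(x$triangles)))
  invisible(x)
}

#' Edge list of a triangulation (for plotting or export)
#'
#' @param dt A [build_delaunay()] object.
#' @return A tibble of unique edges with endpoint indices and coordinates.
#' @export
delaunay_edges <- function(dt) {
  tr <- dt$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(1L, 3L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  tibble::tibble(
    from = e[, 1L], to = e[, 2L],
    x0 = dt$points[e[, 1L], 1L], y0 = dt$points[e[, 1L], 2L],
    x1 = dt$points[e[, 2L], 1L], y1 = dt$points[e[, 2L], 2L])
}
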