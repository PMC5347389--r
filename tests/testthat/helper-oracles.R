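# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately brute-force and independent of the code
# paths it checks.

# count empty-circumcircle violations by testing every (triangle, point)
# pair directly
brute_circumcircle_violations <- function(xy, triangles, rel_tol = 1e-9) {
  viol <- 0L
  for (t in seq_len(nrow(triangles))) {
    v <- triangles[t, ]
    ax <- xy[v[1L], 1L]; ay <- xy[v[1L], 2L]
    bx <- xy[v[2L], 1L]; by <- xy[v[2L], 2L]
    cx <- xy[v[3L], 1L]; cy <- xy[v[3L], 2L]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
    r2 <- (ux - ax)^2 + (uy - ay)^2
    others <- setdiff(seq_len(nrow(xy)), v)
    d2 <- (xy[others, 1L] - ux)^2 + (xy[others, 2L] - uy)^2
    viol <- viol + sum(d2 < r2 * (1 - rel_tol))
  }
  viol
}

# Monte-Carlo stolen-area estimate of Sibson weights: uniform samples in
# the inserted cell V(q), classified by their nearest original site. The
# sampling box starts just beyond the nearest site and doubles until the
# accepted region no longer touches its boundary (so V(q) is fully
# enclosed however small or elongated it is), capped at the same clipping
# box the tessellation uses; batches are then drawn in the padded tight
# box until n_target samples land in V(q).
mc_sibson_weights <- function(pts, q, n_target = 1e5, expand = 3) {
  n <- nrow(pts)
  nearest_is_q <- function(sx, sy) {
    dq <- (sx - q[1L])^2 + (sy - q[2L])^2
    dmin <- rep(Inf, length(sx))
    idx <- integer(length(sx))
    for (i in seq_len(n)) {
      d <- (sx - pts[i, 1L])^2 + (sy - pts[i, 2L])^2
      upd <- d < dmin
      dmin[upd] <- d[upd]
      idx[upd] <- i
    }
    list(in_q = dq < dmin, owner = idx)
  }
  rng_x <- range(pts[, 1L]); rng_y <- range(pts[, 2L])
  diag_len <- sqrt(diff(rng_x)^2 + diff(rng_y)^2)
  clip_x <- rng_x + expand * diag_len * c(-1, 1)
  clip_y <- rng_y + expand * diag_len * c(-1, 1)
  d_near <- sqrt(min((pts[, 1L] - q[1L])^2 + (pts[, 2L] - q[2L])^2))
  # V(q) is convex, so once a sampling window's accepted set stays clear of
  # the window boundary (except where the boundary is the clip box itself),
  # the window encloses V(q); grow until that holds
  wx <- pmax(pmin(q[1L] + 4 * d_near * c(-1, 1), clip_x[2L]), clip_x[1L])
  wy <- pmax(pmin(q[2L] + 4 * d_near * c(-1, 1), clip_y[2L]), clip_y[1L])
  for (iter in 1:40) {
    sx <- runif(1e5, wx[1L], wx[2L]); sy <- runif(1e5, wy[1L], wy[2L])
    cl <- nearest_is_q(sx, sy)
    if (!any(cl$in_q)) {
      wx <- pmax(pmin(wx + diff(wx) * c(-1, 1), clip_x[2L]), clip_x[1L])
      wy <- pmax(pmin(wy + diff(wy) * c(-1, 1), clip_y[2L]), clip_y[1L])
      next
    }
    ax <- range(sx[cl$in_q]); ay <- range(sy[cl$in_q])
    mx <- 0.02 * diff(wx); my <- 0.02 * diff(wy)
    hugging <- (ax[1L] - wx[1L] < mx && wx[1L] > clip_x[1L] + 1e-12) ||
      (wx[2L] - ax[2L] < mx && wx[2L] < clip_x[2L] - 1e-12) ||
      (ay[1L] - wy[1L] < my && wy[1L] > clip_y[1L] + 1e-12) ||
      (wy[2L] - ay[2L] < my && wy[2L] < clip_y[2L] - 1e-12)
    if (!hugging) break
    wx <- pmax(pmin(ax + 1.5 * max(diff(ax), 0.25 * diff(wx)) * c(-1, 1),
                    clip_x[2L]), clip_x[1L])
    wy <- pmax(pmin(ay + 1.5 * max(diff(ay), 0.25 * diff(wy)) * c(-1, 1),
                    clip_y[2L]), clip_y[1L])
  }
  bx <- pmax(pmin(ax + 0.3 * diff(ax) * c(-1, 1) +
                    diag_len * 1e-3 * c(-1, 1), clip_x[2L]), clip_x[1L])
  by <- pmax(pmin(ay + 0.3 * diff(ay) * c(-1, 1) +
                    diag_len * 1e-3 * c(-1, 1), clip_y[2L]), clip_y[1L])
  owners <- integer(0)
  for (batch in 1:100) {
    sx <- runif(1e5, bx[1L], bx[2L]); sy <- runif(1e5, by[1L], by[2L])
    cl <- nearest_is_q(sx, sy)
    owners <- c(owners, cl$owner[cl$in_q])
    if (length(owners) >= n_target) break
  }
  owners <- owners[seq_len(min(length(owners), n_target))]
  tabulate(owners, nbins = n) / length(owners)
}

# a query point guaranteed strictly inside the convex hull: a convex
# combination of three data points with interior barycentric weights
interior_query <- function(xy) {
  v <- sample(nrow(xy), 3L)
  w <- runif(3L, 0.15, 1)
  w <- w / sum(w)
  colSums(xy[v, ] * w)
}

# as interior_query, but rejects draws closer to the convex hull than
# `margin` times the bounding-box diagonal (on structured layouts random
# convex combinations often land on hull edges, where the inserted Voronoi
# cell is unbounded and clipped interpolation is only approximate)
strict_interior_query <- function(xy, margin = 0.02, max_tries = 200L) {
  hull <- grDevices::chull(xy)
  seg_a <- xy[hull, , drop = FALSE]
  seg_b <- xy[c(hull[-1L], hull[1L]), , drop = FALSE]
  diag_len <- sqrt(sum(apply(xy, 2L, function(v) diff(range(v)))^2))
  seg_dist <- function(q) {
    d <- seg_b - seg_a
    t <- ((q[1L] - seg_a[, 1L]) * d[, 1L] + (q[2L] - seg_a[, 2L]) * d[, 2L]) /
      pmax(rowSums(d^2), 1e-300)
    t <- pmin(pmax(t, 0), 1)
    px <- seg_a[, 1L] + t * d[, 1L]
    py <- seg_a[, 2L] + t * d[, 2L]
    min(sqrt((q[1L] - px)^2 + (q[2L] - py)^2))
  }
  for (i in seq_len(max_tries)) {
    q <- interior_query(xy)
    if (seg_dist(q) > margin * diag_len) return(q)
  }
  stop("no strictly interior query found")
}

# small standard synthetic system used by several files (3 exposure times
# to keep unit tests quick; acceptance uses the full 7-time design)
quick_system <- function(seed = 1L, times = c(2, 6, 12), ...) {
  simulate_mixture_system(times = times, seed = seed, ...)
}
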