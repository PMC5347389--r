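test_that("small configurations triangulate as expected", {
  tri3 <- build_delaunay(rbind(c(0, 0), c(1, 0), c(0.3, 1)))
  expect_equal(nrow(tri3$triangles), 1L)
  sq <- build_delaunay(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(sq$triangles), 2L)
  expect_error(build_delaunay(cbind(1:5, 2 * (1:5))),
               class = "mixray_geometry_error")
  expect_error(build_delaunay(rbind(c(0, 0), c(0, 0), c(1, 1))),
               class = "mixray_geometry_error")
})

test_that("random clouds satisfy the empty-circumcircle property", {
  set.seed(31)
  for (i in 1:4) {
    xy <- cbind(runif(50), runif(50))
    dt <- build_delaunay(xy)
    expect_identical(brute_circumcircle_violations(xy, dt$triangles), 0L)
  }
})

test_that("triangulation agrees with an independent implementation", {
  skip_if_not_installed("deldir")
  set.seed(13)
  for (i in 1:3) {
    xy <- cbind(runif(40), runif(40))
    dt <- build_delaunay(xy)
    tl <- deldir::triang.list(deldir::deldir(xy[, 1], xy[, 2]))
    ref <- t(vapply(tl, function(tt) sort(tt$ptNum), integer(3L)))
    ref <- ref[order(ref[, 1], ref[, 2], ref[, 3]), , drop = FALSE]
    expect_identical(unname(dt$triangles), unname(ref))
  }
})

test_that("linear interpolation has linear precision and honours the hull", {
  set.seed(17)
  xy <- cbind(runif(30), runif(30))
  z <- 2 * xy[, 1] - 3 * xy[, 2] + 1
  dt <- build_delaunay(xy)
  # training vertices reproduce exactly
  expect_equal(linear_interpolate(dt, xy, z), z, tolerance = 1e-9)
  q <- t(replicate(100, interior_query(xy)))
  expect_equal(linear_interpolate(dt, q, z), 2 * q[, 1] - 3 * q[, 2] + 1,
               tolerance = 1e-9)
  # centroid of a triangle with values (0, 0, 3) -> barycentric mean 1
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(linear_interpolate(build_delaunay(tri),
                                  colMeans(tri), c(0, 0, 3)), 1,
               tolerance = 1e-12)
  # far outside the hull: refused, not extrapolated
  expect_true(is.na(linear_interpolate(dt, c(5, 5), z)))
})

test_that("voronoi cells own their sites and partition by nearest distance", {
  set.seed(23)
  xy <- cbind(runif(25), runif(25))
  vor <- build_voronoi(xy)
  # convex-polygon membership test against the cells reported in data
  # coordinates by voronoi_polygons()
  polys <- voronoi_polygons(vor)
  in_cell <- function(i, pt) {
    cell <- as.matrix(polys[polys$cell == i, c("x", "y")])
    all(vapply(seq_len(nrow(cell)), function(k) {
      j <- if (k == nrow(cell)) 1L else k + 1L
      e <- cell[j, ] - cell[k, ]
      e[1] * (pt[2] - cell[k, 2]) - e[2] * (pt[1] - cell[k, 1]) >= -1e-9
    }, logical(1L)))
  }
  # every site inside its own cell
  for (i in seq_len(25)) expect_true(in_cell(i, xy[i, ]))
  # nearest-site ownership at random interior locations
  q <- t(replicate(150, interior_query(xy)))
  for (k in seq_len(nrow(q))) {
    d2 <- (xy[, 1] - q[k, 1])^2 + (xy[, 2] - q[k, 2])^2
    expect_true(in_cell(which.min(d2), q[k, ]))
  }
  # 2x2 grid: cell boundaries are the perpendicular bisectors
  g <- build_voronoi(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
  w <- sibson_weights(g, c(1, 1))
  expect_equal(w$weight, rep(0.25, 4))
})

test_that("sibson weights are a convex combination matching the MC oracle", {
  set.seed(47)
  worst_sum <- 0
  for (i in 1:8) {
    n <- sample(8:16, 1)
    xy <- cbind(runif(n), runif(n))
    vor <- build_voronoi(xy)
    q <- interior_query(xy)
    w <- sibson_weights(vor, q)
    expect_true(all(w$weight >= 0))
    worst_sum <- max(worst_sum, abs(sum(w$weight) - 1))
    wm <- mc_sibson_weights(xy, q, n_target = 1e5)
    full <- numeric(n)
    full[w$index] <- w$weight
    expect_lt(mean(abs(full - wm)), 2e-3)
  }
  expect_lt(worst_sum, 1e-9)
})

test_that("sibson edge cases: coincident vertex and outside queries", {
  set.seed(3)
  xy <- cbind(runif(12), runif(12))
  vor <- build_voronoi(xy)
  hit <- sibson_weights(vor, xy[5, ])
  expect_equal(hit$index, 5L)
  expect_equal(hit$weight, 1)
  expect_null(sibson_weights(vor, c(10, 10)))
  expect_true(is.na(natural_neighbor_interpolate(vor, c(10, 10), runif(12))))
})

test_that("natural-neighbour interpolation is exact on affine fields", {
  set.seed(29)
  xy <- cbind(runif(20), runif(20))
  vor <- build_voronoi(xy)
  z <- xy[, 1] + xy[, 2]
  q <- t(replicate(50, interior_query(xy)))
  expect_equal(natural_neighbor_interpolate(vor, q, z),
               q[, 1] + q[, 2], tolerance = 1e-6)
  # constant field: exactly the constant (weights sum to 1)
  expect_equal(natural_neighbor_interpolate(vor, q, rep(7, 20)),
               rep(7, 50), tolerance = 1e-9)
  # vertex query returns the vertex value
  expect_equal(natural_neighbor_interpolate(vor, xy[3, ], z), z[3])
})

test_that("interpolated values never overshoot the participating vertices", {
  set.seed(59)
  xy <- cbind(runif(30), runif(30))
  z <- sin(4 * xy[, 1]) + cos(3 * xy[, 2])
  dt <- build_delaunay(xy)
  vor <- build_voronoi(xy)
  q <- t(replicate(80, interior_query(xy)))
  lin <- linear_interpolate(dt, q, z)
  nn <- natural_neighbor_interpolate(vor, q, z)
  expect_true(all(lin >= min(z) - 1e-9 & lin <= max(z) + 1e-9))
  expect_true(all(nn >= min(z) - 1e-9 & nn <= max(z) + 1e-9))
})

test_that("predictions are invariant to training point order", {
  set.seed(61)
  xy <- cbind(runif(25), runif(25))
  z <- xy[, 1]^2 + xy[, 2]
  q <- t(replicate(20, interior_query(xy)))
  perm <- sample(25)
  dt1 <- build_delaunay(xy); dt2 <- build_delaunay(xy[perm, ])
  vor1 <- build_voronoi(xy); vor2 <- build_voronoi(xy[perm, ])
  expect_equal(linear_interpolate(dt1, q, z),
               linear_interpolate(dt2, q, z[perm]), tolerance = 1e-9)
  expect_equal(natural_neighbor_interpolate(vor1, q, z),
               natural_neighbor_interpolate(vor2, q, z[perm]),
               tolerance = 1e-9)
})

test_that("clipping margin does not affect hull-interior weights", {
  set.seed(67)
  xy <- cbind(runif(15), runif(15))
  q <- interior_query(xy)
  w3 <- sibson_weights(build_voronoi(xy, expand = 3), q)
  w6 <- sibson_weights(build_voronoi(xy, expand = 6), q)
  expect_equal(w3, w6, tolerance = 1e-12)
})
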