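test_that("holdout split has the protocol sizes and is seed-deterministic", {
  sys <- quick_system(seed = 21, times = c(2, 12))
  sp <- lmocv_split(sys, seed = 1)
  per_time_test <- dplyr::count(sp$test, time_h)
  per_time_train <- dplyr::count(sp$train, time_h)
  expect_equal(unique(per_time_test$n), 20L)  # 1/3 of 60 mixture points
  expect_equal(unique(per_time_train$n), 64L) # 40 mixture + 24/... singles
  expect_true(all(sp$test$role == "ray"))
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(sys))
  expect_equal(nrow(dplyr::intersect(sp$train, sp$test)), 0L)
  sp2 <- lmocv_split(sys, seed = 1)
  expect_identical(sp$test, sp2$test)
  sp3 <- lmocv_split(sys, seed = 2)
  expect_false(identical(sp$test, sp3$test))
  expect_error(lmocv_split(sys, strict = TRUE), class = "mixray_config_error")
})

test_that("accuracy rate counts closed-interval CI overlap", {
  expect_equal(accuracy_rate(c(1, 2, 3), c(0, 0, 0), c(5, 5, 5)), 100)
  expect_equal(accuracy_rate(c(1, 9), c(0, 0), c(5, 5)), 50)
  # boundary predictions count as correct
  expect_equal(accuracy_rate(5, 0, 5), 100)
  expect_equal(accuracy_rate(0, 0, 5), 100)
  # NA predictions are not evaluated
  expect_equal(accuracy_rate(c(NA, 1), c(0, 0), c(5, 5)), 100)
  expect_error(accuracy_rate(NA_real_, 0, 5), class = "mixray_metric_error")
  # order invariance and monotonicity under shrinking CIs
  set.seed(10)
  pred <- rnorm(60, 50, 5); obs <- rnorm(60, 50, 5)
  half <- abs(rnorm(60, 8, 2))
  ar <- vapply(c(1, 0.6, 0.3, 0.05), function(s) {
    accuracy_rate(pred, obs - s * half, obs + s * half)
  }, numeric(1))
  expect_true(all(diff(ar) <= 0))
  perm <- sample(60)
  expect_equal(accuracy_rate(pred[perm], (obs - half)[perm], (obs + half)[perm]),
               accuracy_rate(pred, obs - half, obs + half))
})

test_that("rmse and r-squared follow their standard definitions", {
  obs <- c(10, 20, 30, 40)
  expect_equal(rmse_metric(obs, obs), 0)
  expect_equal(r2_metric(obs, obs), 1)
  expect_equal(rmse_metric(obs + 2, obs), 2)
  expect_lt(r2_metric(rev(obs), obs), 0) # anti-correlated: negative R2 allowed
  expect_error(r2_metric(c(1, 2), c(5, 5)), class = "mixray_metric_error")
  expect_error(rmse_metric(1, 1), class = "mixray_metric_error")
})

test_that("a noise-free linear toxicity surface is cross-validated perfectly", {
  sys <- simulate_mixture_system(times = 6, noise_sd = 0, n_replicates = 1,
                                 seed = 33)
  # replace the effect surface by an affine field of the raw concentrations
  # (interpolation has linear precision, so every holdout is exact)
  sys$effect <- 2e4 * sys$conc_a - 1e4 * sys$conc_b + 5
  # tight CIs: far narrower than any replicate-based interval
  sys$ci_lo <- sys$effect - 0.5
  sys$ci_hi <- sys$effect + 0.5
  cv <- lmocv(sys, n_repeats = 3, seed = 14, coordinate_space = "linear")
  gl <- generics::glance(cv)
  expect_equal(gl$ar, c(100, 100))
  expect_true(all(gl$r_squared > 1 - 1e-4))
  # the triangulation route is exact everywhere; the natural-neighbour
  # route is exact in the hull interior but sub-percent approximate for
  # holdouts next to the hull, where the inserted cell must be clipped
  expect_lt(gl$rmse[gl$method == "linip"], 1e-9)
  expect_lt(gl$rmse[gl$method == "neiip"], 0.2)
})

test_that("noise-free curved surfaces are recovered to interpolation accuracy", {
  sys <- simulate_mixture_system(times = 6, noise_sd = 0, n_replicates = 1,
                                 seed = 33)
  cv <- lmocv(sys, n_repeats = 3, seed = 14)
  gl <- generics::glance(cv)
  # residual error is pure interpolation curvature over one dilution step
  expect_true(all(gl$r_squared > 0.99))
  expect_true(all(gl$rmse < 2))
})

test_that("lmocv aggregates repeats reproducibly", {
  sys <- quick_system(seed = 22)
  cv1 <- lmocv(sys, n_repeats = 4, seed = 9)
  cv2 <- lmocv(sys, n_repeats = 4, seed = 9)
  expect_identical(generics::glance(cv1), generics::glance(cv2))
  td <- generics::tidy(cv1)
  expect_equal(nrow(td), 4L * 2L) # repeats x methods
  expect_true(all(td$ar >= 0 & td$ar <= 100))
  # per-repeat variation exists (different random splits)
  expect_gt(stats::sd(td$ar[td$method == "linip"]), 0)
  gl <- generics::glance(cv1)
  expect_equal(gl$ar, tapply(td$ar, td$method, mean)[gl$method],
               ignore_attr = TRUE)
  expect_s3_class(ggplot2::autoplot(cv1), "ggplot")
})

test_that("leave-one-ray-out is deterministic with one fold per ray", {
  sys <- quick_system(seed = 23, times = c(6, 12))
  lo1 <- loocv_by_ray(sys)
  lo2 <- loocv_by_ray(sys)
  expect_identical(generics::glance(lo1), generics::glance(lo2))
  expect_equal(sort(lo1$folds), paste0("R", 1:5))
  td <- generics::tidy(lo1)
  expect_equal(nrow(td), 5L * 2L)
  # each fold predicts the complete left-out ray: 12 levels x 2 times
  per_fold <- dplyr::count(lo1$per_point, fold)
  expect_equal(unique(per_fold$n), 24L)
  # edge rays lose more points to the hull than the middle ray
  outs <- lo1$per_point |>
    dplyr::group_by(fold) |>
    dplyr::summarise(n_out = sum(outside))
  expect_gte(outs$n_out[outs$fold == "R1"], outs$n_out[outs$fold == "R3"])
  expect_error(loocv_by_ray(dplyr::filter(sys, id %in% c("A", "B", "R1"))),
               class = "mixray_input_error")
})
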