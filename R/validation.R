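#' Confidence-interval overlap accuracy rate
#'
#' A prediction is correct when it falls inside the observed 95%
#' confidence interval (closed at both bounds). The accuracy rate is the
#' percentage of evaluated predictions that are correct; `NA` predictions
#' (queries the interpolator refused, e.g. outside the hull) are not
#' evaluated.
#'
#' @param pred Predicted effects, percent.
#' @param ci_lo,ci_hi Observed CI bounds.
#' @return Accuracy rate in percent.
#' @export
accuracy_rate <- function(pred, ci_lo, ci_hi) {
  ok <- is.finite(pred)
  if (!any(ok)) {
    abort("no evaluable predictions; accuracy rate undefined.",
          class = "mixray_metric_error")
  }
  100 * mean(pred[ok] >= ci_lo[ok] & pred[ok] <= ci_hi[ok])
}

#' Root mean square error of predictions (percent effect)
#'
#' @param pred,obs Predicted and observed effects, percent. `NA`
#'   predictions are dropped pairwise.
#' @return RMSE in percent effect.
#' @export
rmse_metric <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 2L) {
    abort("need at least 2 evaluable pairs.", class = "mixray_metric_error")
  }
  sqrt(mean((pred[ok] - obs[ok])^2))
}

#' Coefficient of determination of predictions
#'
#' `R^2 = 1 - SS_res / SS_tot` against the observed mean; may be negative
#' for predictions worse than the mean.
#'
#' @inheritParams rmse_metric
#' @return Unitless R-squared.
#' @export
r2_metric <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 2L) {
    abort("need at least 2 evaluable pairs.", class = "mixray_metric_error")
  }
  ss_tot <- sum((obs[ok] - mean(obs[ok]))^2)
  if (ss_tot < .Machine$double.eps) {
    abort("observed effects have zero variance; R^2 undefined.",
          class = "mixray_metric_error")
  }
  1 - sum((pred[ok] - obs[ok])^2) / ss_tot
}

#' Random holdout split of a mixture system
#'
#' Partitions the mixture points of one system into a test set
#' (approximately 1/3) and a training set containing the remaining
#' mixture points plus all single-compound points (singles are never held
#' out). The split is drawn on (ray, dilution level) identities and is
#' shared across exposure times, matching the protocol of 60 mixture
#' points per time split into 20 test and 40 training, plus 24 singles.
#'
#' @param data Tidy system dataset with columns `id`, `role`, `level`,
#'   `time_h`, ...
#' @param prop_test Fraction of mixture points held out (default 1/3;
#'   rounded to the nearest integer count).
#' @param seed Integer seed; required when `strict = TRUE`.
#' @param strict Require a seed for exact reproducibility.
#' @return A list with tibbles `train` and `test`.
#' @export
lmocv_split <- function(data, prop_test = 1 / 3, seed = NULL, strict = FALSE) {
  if (strict && is.null(seed)) {
    abort("`seed` is required in strict-reproducibility mode.",
          class = "mixray_config_error")
  }
  ids <- dplyr::distinct(
    dplyr::filter(data, .data$role == "ray"), .data$id, .data$level)
  n_mix <- nrow(ids)
  if (!n_mix) abort("no mixture points to split.", class = "mixray_input_error")
  n_test <- round(n_mix * prop_test)
  pick <- with_seed(seed, sample.int(n_mix, n_test))
  test_ids <- ids[pick, ]
  is_test <- data$role == "ray" &
    paste(data$id, data$level) %in% paste(test_ids$id, test_ids$level)
  list(train = tibble::as_tibble(data[!is_test, , drop = FALSE]),
       test = tibble::as_tibble(data[is_test, , drop = FALSE]))
}

validation_metrics <- function(pp) {
  pp |>
    tidyr::pivot_longer(dplyr::any_of(c("pred_linip", "pred_neiip")),
                        names_to = "method", names_prefix = "pred_",
                        values_to = "pred") |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      ar = accuracy_rate(.data$pred, .data$ci_lo, .data$ci_hi),
      rmse = rmse_metric(.data$pred, .data$effect),
      r_squared = r2_metric(.data$pred, .data$effect),
      n_eval = sum(is.finite(.data$pred)),
      n_outside = sum(!is.finite(.data$pred)),
      .groups = "drop")
}

#' Repeated random-holdout cross-validation (LMOCV)
#'
#' Repeats the [lmocv_split()] holdout `n_repeats` times, each time
#' rebuilding the per-time interpolation models from the training portion
#' and predicting the held-out mixture points, and scores each repeat by
#' CI-overlap accuracy rate, RMSE and R-squared (pooled over exposure
#' times within the repeat). Held-out points outside the training convex
#' hull are counted separately and excluded from the metric denominators.
#'
#' @param data Tidy system dataset (all exposure times).
#' @param method `"both"` (default), `"linip"` or `"neiip"`.
#' @param n_repeats Number of random holdouts (default 20).
#' @param seed Master seed; per-repeat seeds are spawned from it.
#' @param coordinate_space Passed to [build_interpolator()].
#' @param prop_test Held-out fraction of mixture points.
#' @return A `mix_validation` object: per-repeat metrics, per-point
#'   records, and the across-repeat mean summary. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
lmocv <- function(data, method = c("both", "linip", "neiip"),
                  n_repeats = 20L, seed = NULL,
                  coordinate_space = c("log10", "linear"),
                  prop_test = 1 / 3) {
  method <- match.arg(method)
  coordinate_space <- match.arg(coordinate_space)
  repeat_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                             n_repeats))
  per_point <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    sp <- lmocv_split(data, prop_test = prop_test, seed = repeat_seeds[r])
    pred <- predict_toxicity(sp$train, sp$test, method = method,
                             coordinate_space = coordinate_space)
    pred$repeat_id <- r
    pred
  })
  per_repeat <- per_point |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::group_modify(~ validation_metrics(.x)) |>
    dplyr::ungroup()
  summary <- per_repeat |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(c("ar", "rmse", "r_squared"), mean),
                     n_outside = sum(.data$n_outside), .groups = "drop")
  structure(
    list(scheme = "LMOCV", method = method, n_repeats = n_repeats,
         seed = seed, repeat_seeds = repeat_seeds,
         per_repeat = per_repeat, per_point = per_point, summary = summary),
    class = "mix_validation")
}

#' Leave-one-ray-out cross-validation (LOOCV)
#'
#' For each mixture ray in turn, trains on the remaining rays plus both
#' single compounds and predicts the complete left-out ray at every
#' dilution level and exposure time. Deterministic (no randomness).
#'
#' @inheritParams lmocv
#' @return A `mix_validation` object with per-fold (per-ray) metrics and
#'   the pooled summary over all left-out points.
#' @export
loocv_by_ray <- function(data, method = c("both", "linip", "neiip"),
                         coordinate_space = c("log10", "linear")) {
  method <- match.arg(method)
  coordinate_space <- match.arg(coordinate_space)
  rays <- sort(unique(data$id[data$role == "ray"]))
  if (length(rays) < 2L) {
    abort("need at least 2 rays for leave-one-ray-out.",
          class = "mixray_input_error")
  }
  per_point <- purrr::map_dfr(rays, function(rr) {
    train <- dplyr::filter(data, .data$role == "single" | .data$id != rr)
    test <- dplyr::filter(data, .data$id == rr)
    pred <- predict_toxicity(train, test, method = method,
                             coordinate_space = coordinate_space)
    pred$fold <- rr
    pred
  })
  per_fold <- per_point |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(~ validation_metrics(.x)) |>
    dplyr::ungroup()
  summary <- validation_metrics(per_point)
  structure(
    list(scheme = "LOOCV", method = method, folds = rays,
         per_fold = per_fold, per_point = per_point, summary = summary),
    class = "mix_validation")
}

#' @export
print.mix_validation <- function(x, ...) {
  cat(sprintf("<mix_validation> %s\n", x$scheme))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.mix_validation <- function(x, ...) {
  if (x$scheme == "LMOCV") x$per_repeat else x$per_fold
}

#' @export
glance.mix_validation <- function(x, ...) {
  dplyr::mutate(x$summary, scheme = x$scheme, .before = 1L)
}
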