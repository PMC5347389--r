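#' Build a mixture-toxicity interpolation model
#'
#' Turns the concentration-toxicity training points of one binary mixture
#' system at one exposure time — the two single compounds and the mixture
#' rays, each tested over a dilution series — into a queryable spatial
#' model: the Delaunay triangulation (for linear interpolation) and the
#' Voronoi tessellation (for Sibson natural-neighbour interpolation) of
#' the vertices in the concentration plane.
#'
#' Interpolation is done on decadic-log concentration axes by default,
#' where a geometric dilution series is evenly spaced; this is the model's
#' most consequential geometric choice and can be switched to raw linear
#' axes. A single compound has zero concentration of the partner compound,
#' which has no logarithm; such coordinates are mapped to an axis floor,
#' by default one dilution step below the lowest tested concentration on
#' that axis (the step is estimated from the data's own spacing).
#'
#' @param data Data frame with one row per training point: columns
#'   `conc_a`, `conc_b`, `effect` (percent), optionally `ci_lo`, `ci_hi`
#'   and identifiers.
#' @param coordinate_space `"log10"` (default) or `"linear"`.
#' @param axis_floor Optional length-2 numeric, the concentration that
#'   zero maps to on each axis under log coordinates; `NULL` estimates it
#'   from the data.
#' @return An object of class `mix_interpolator` with the training tibble,
#'   the coordinate mapping, and the two geometric structures. Supports
#'   [predict()] and [ggplot2::autoplot()].
#' @export
build_interpolator <- function(data, coordinate_space = c("log10", "linear"),
                               axis_floor = NULL) {
  coordinate_space <- match.arg(coordinate_space)
  need <- c("conc_a", "conc_b", "effect")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns %s.", paste(need, collapse = ", ")),
          class = "mixray_input_error")
  }
  if (!nrow(data)) abort("empty training set.", class = "mixray_input_error")
  if (any(data$conc_a < 0 | data$conc_b < 0) ||
      any(data$conc_a == 0 & data$conc_b == 0)) {
    abort("concentrations must be non-negative and not both zero.",
          class = "mixray_input_error")
  }
  floors <- c(NA_real_, NA_real_)
  if (coordinate_space == "log10") {
    floors <- c(
      axis_floor[1L] %||% estimate_axis_floor(data$conc_a),
      if (length(axis_floor) == 2L) axis_floor[2L] else estimate_axis_floor(data$conc_b)
    )
  }
  xy <- transform_coords(data$conc_a, data$conc_b, coordinate_space, floors)
  if (anyDuplicated(xy)) {
    abort("duplicate (conc_a, conc_b) training coordinates.",
          class = "mixray_input_error")
  }
  vor <- build_voronoi(xy)
  structure(
    list(training = tibble::as_tibble(data),
         coordinate_space = coordinate_space,
         axis_floor = floors,
         values = data$effect,
         voronoi = vor,
         delaunay = vor$delaunay),
    class = "mix_interpolator")
}

# one geometric dilution step below the lowest positive concentration;
# step estimated from the median spacing of the data's own series
estimate_axis_floor <- function(conc) {
  pos <- sort(unique(conc[conc > 0]))
  if (!length(pos)) return(NA_real_)
  if (length(pos) == 1L) return(pos / 2)
  step <- stats::median(diff(lg(pos)))
  10^(lg(pos[1L]) - step)
}

transform_coords <- function(conc_a, conc_b, space, floors) {
  if (space == "linear") return(cbind(x = conc_a, y = conc_b))
  xa <- ifelse(conc_a > 0, conc_a, floors[1L])
  xb <- ifelse(conc_b > 0, conc_b, floors[2L])
  if (any(!is.finite(xa)) || any(!is.finite(xb))) {
    abort("zero concentration with no axis floor available.",
          class = "mixray_input_error")
  }
  cbind(x = lg(xa), y = lg(xb))
}

#' @export
print.mix_interpolator <- function(x, ...) {
  cat(sprintf(
    "<mix_interpolator> %d training vertices, %d triangles, %s axes\n",
    nrow(x$training), nrow(x$delaunay$triangles), x$coordinate_space))
  if (x$coordinate_space == "log10" && any(is.finite(x$axis_floor))) {
    cat(sprintf("  axis floor for zero concentrations: A %.3g, B %.3g mol/L\n",
                x$axis_floor[1L], x$axis_floor[2L]))
  }
  invisible(x)
}

#' Predict mixture toxicity at query concentrations
#'
#' Interpolates the toxicity surface at new (conc_a, conc_b) points by
#' linear interpolation over the Delaunay triangulation (`linip`), Sibson
#' natural-neighbour interpolation over the Voronoi tessellation
#' (`neiip`), or both. Queries outside the convex hull of the training
#' set are flagged `outside` and never extrapolated.
#'
#' @param object A [build_interpolator()] model.
#' @param newdata Data frame with columns `conc_a` and `conc_b`.
#' @param method `"both"` (default), `"linip"` or `"neiip"`.
#' @param ... Unused.
#' @return `newdata` as a tibble with added columns `outside` and
#'   `pred_linip` / `pred_neiip` (percent effect; `NA` outside the hull).
#' @export
predict.mix_interpolator <- function(object, newdata,
                                     method = c("both", "linip", "neiip"),
                                     ...) {
  method <- match.arg(method)
  if (!all(c("conc_a", "conc_b") %in% names(newdata))) {
    abort("`newdata` must have columns conc_a and conc_b.",
          class = "mixray_input_error")
  }
  qm <- transform_coords(newdata$conc_a, newdata$conc_b,
                         object$coordinate_space, object$axis_floor)
  out <- tibble::as_tibble(newdata)
  if (method %in% c("both", "linip")) {
    out$pred_linip <- linear_interpolate(object$delaunay, qm, object$values)
  }
  if (method %in% c("both", "neiip")) {
    out$pred_neiip <- natural_neighbor_interpolate(object$voronoi, qm,
                                                   object$values)
  }
  pred_cols <- intersect(c("pred_linip", "pred_neiip"), names(out))
  out$outside <- Reduce(`&`, lapply(pred_cols, function(cl) is.na(out[[cl]])))
  out
}

#' Predict toxicity per exposure time across a whole dataset
#'
#' Convenience wrapper that builds one interpolation model per exposure
#' time from a tidy dataset and predicts matching-time queries. Exposure
#' time is a grouping key, not an interpolation axis: each time's surface
#' is independent.
#'
#' @param training Tidy dataset (columns `conc_a`, `conc_b`, `effect`,
#'   `time_h`, ...), e.g. from [simulate_mixture_system()].
#' @param queries Data frame with `conc_a`, `conc_b`, `time_h`.
#' @param method `"both"`, `"linip"` or `"neiip"`.
#' @param coordinate_space Passed to [build_interpolator()].
#' @return `queries` with prediction columns, as a tibble.
#' @export
predict_toxicity <- function(training, queries,
                             method = c("both", "linip", "neiip"),
                             coordinate_space = c("log10", "linear")) {
  method <- match.arg(method)
  coordinate_space <- match.arg(coordinate_space)
  if (!nrow(training)) abort("empty training set.", class = "mixray_input_error")
  times <- sort(unique(queries$time_h))
  missing_t <- setdiff(times, unique(training$time_h))
  if (length(missing_t)) {
    abort(sprintf("no training data for time(s): %s",
                  paste(missing_t, collapse = ", ")),
          class = "mixray_input_error")
  }
  purrr::map_dfr(times, function(tt) {
    mod <- build_interpolator(
      dplyr::filter(training, .data$time_h == tt),
      coordinate_space = coordinate_space)
    predict(mod, dplyr::filter(queries, .data$time_h == tt), method = method)
  })
}
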