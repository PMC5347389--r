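#' Monotonic Weibull concentration-response function
#'
#' Effect (% inhibition) of a single compound under the two-parameter
#' Weibull model on the decadic-log concentration scale,
#' `E = 100 * (1 - exp(-exp(alpha + beta * lg c)))`.
#'
#' @param conc Concentration (mol/L), strictly positive. Vectorised.
#' @param alpha Location parameter (intercept on the lg-concentration scale).
#' @param beta Slope parameter on the lg-concentration scale; `beta > 0`
#'   gives a curve increasing from 0 to 100%.
#' @return Numeric vector of effects in percent, in (0, 100).
#' @examples
#' effect_weibull(1, alpha = 0, beta = 1) # ~63.212
#' @export
effect_weibull <- function(conc, alpha, beta) {
  check_positive(conc, "conc")
  100 * (1 - exp(-exp(alpha + beta * lg(conc))))
}

#' Monotonic Logit concentration-response function
#'
#' `E = 100 / (1 + exp(-alpha - beta * lg c))`.
#'
#' @inheritParams effect_weibull
#' @return Numeric vector of effects in percent, in (0, 100).
#' @examples
#' effect_logit(1, alpha = 0, beta = 2) # 50
#' @export
effect_logit <- function(conc, alpha, beta) {
  check_positive(conc, "conc")
  100 / (1 + exp(-alpha - beta * lg(conc)))
}

# rising logistic limb on the lg-concentration scale: 0 -> 1, value 1/2 at
# lg c = le, shape b > 0
logistic_limb <- function(lgc, le, b) {
  1 / (1 + 10^(-b * (lgc - le)))
}

fivepl_eval_internal <- function(conc, internal) {
  lgc <- lg(conc)
  internal$m * logistic_limb(lgc, internal$le1, internal$b1) +
    (100 - internal$m) * logistic_limb(lgc, internal$le2, internal$b2)
}

# locate the interior minimum of the J-shaped curve: coarse grid then local
# refinement (the curve has exactly one interior minimum when it dips < 0)
fivepl_minimum <- function(internal) {
  lo <- min(internal$le1 - 6 / internal$b1, internal$le1 - 2)
  hi <- internal$le2 + 1
  grid <- seq(lo, hi, length.out = 400L)
  vals <- fivepl_eval_internal(10^grid, internal)
  i <- which.min(vals)
  i_lo <- max(1L, i - 1L)
  i_hi <- min(length(grid), i + 1L)
  opt <- optimize(function(u) fivepl_eval_internal(10^u, internal),
                  interval = c(grid[i_lo], grid[i_hi]), tol = 1e-12)
  list(lg_ec_min = opt$minimum, e_min = opt$objective)
}

#' Construct a parameter set for the J-shaped (hormetic) response model
#'
#' The J-shaped concentration-response model is a five-parameter
#' double-logistic on the lg-concentration scale: a stimulatory (falling)
#' limb scaled by `e_min` plus an inhibitory (rising) limb to 100%. The
#' user-facing parameters carry the published semantics: `e_min` is the
#' minimum (most stimulatory) effect; `eps_dn` is the concentration at
#' effect `e_min/2` on the falling limb and `beta_dn` the shape of that
#' limb; `eps_up` is the median effective concentration (effect 50%) and
#' `beta_up` the shape of the rising limb. The three internal location/scale
#' constants are solved numerically so these semantics hold exactly.
#'
#' @param e_min Minimum effect in percent; must be negative (stimulation).
#' @param eps_dn Concentration (mol/L) at effect `e_min/2` on the falling limb.
#' @param beta_dn Shape of the falling limb (> 0).
#' @param eps_up Median effective concentration (mol/L); effect 50%.
#' @param beta_up Shape of the rising limb (> 0).
#' @return An object of class `fivepl_params`: the five semantic parameters
#'   plus the anchored internal coefficients.
#' @examples
#' p <- fivepl_params(e_min = -20, eps_dn = 1e-5, beta_dn = 1.5,
#'                    eps_up = 1e-3, beta_up = 2)
#' effect_fivepl(c(1e-5, 1e-3), p) # -10, 50
#' @export
fivepl_params <- function(e_min, eps_dn, beta_dn, eps_up, beta_up) {
  check_scalar_number(e_min, "e_min")
  check_positive(c(eps_dn, eps_up, beta_dn, beta_up), "eps_dn/eps_up/beta_dn/beta_up")
  if (e_min >= 0) {
    abort("`e_min` must be negative (a stimulatory minimum).",
          class = "mixray_parameter_error")
  }
  if (eps_dn >= eps_up) {
    abort("`eps_dn` must be smaller than `eps_up`.",
          class = "mixray_parameter_error")
  }
  target <- list(e_min = e_min, eps_dn = eps_dn, beta_dn = beta_dn,
                 eps_up = eps_up, beta_up = beta_up)
  internal <- fivepl_anchor(target)
  structure(c(target, list(internal = internal)), class = "fivepl_params")
}

# solve (m, le1, le2) so that effect(eps_dn) = e_min/2, effect(eps_up) = 50
# and min effect = e_min, with limb shapes fixed at (beta_dn, beta_up)
fivepl_anchor <- function(p) {
  resid_fun <- function(par) {
    internal <- list(m = par[[1L]], le1 = par[[2L]], b1 = p$beta_dn,
                     le2 = par[[3L]], b2 = p$beta_up)
    if (internal$le1 >= internal$le2) return(rep(1e6, 3L))
    c(fivepl_eval_internal(p$eps_dn, internal) - p$e_min / 2,
      fivepl_eval_internal(p$eps_up, internal) - 50,
      fivepl_minimum(internal)$e_min - p$e_min)
  }
  start <- c(p$e_min, lg(p$eps_dn), lg(p$eps_up))
  sol <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (max(abs(sol$fvec)) > 1e-6) {
    abort(paste("Could not anchor the J-shaped model to the requested",
                "parameters; the stimulatory and inhibitory limbs are not",
                "separable (try a larger eps_up/eps_dn ratio)."),
          class = "mixray_parameter_error")
  }
  list(m = sol$par[[1L]], le1 = sol$par[[2L]], b1 = p$beta_dn,
       le2 = sol$par[[3L]], b2 = p$beta_up)
}

#' J-shaped (hormetic) concentration-response function
#'
#' @inheritParams effect_weibull
#' @param params A [fivepl_params()] object, or a list with elements
#'   `e_min`, `eps_dn`, `beta_dn`, `eps_up`, `beta_up`.
#' @return Numeric vector of effects in percent; negative in the
#'   stimulation zone, approaching 100 at high concentration.
#' @export
effect_fivepl <- function(conc, params) {
  check_positive(conc, "conc")
  if (!inherits(params, "fivepl_params")) {
    params <- fivepl_params(params$e_min, params$eps_dn, params$beta_dn,
                            params$eps_up, params$beta_up)
  }
  fivepl_eval_internal(conc, params$internal)
}

# ---------------------------------------------------------------------------
# fitting

crc_curve_fun <- function(family, coefs, internal = NULL) {
  switch(family,
    weibull = function(conc) effect_weibull(conc, coefs[["alpha"]], coefs[["beta"]]),
    logit   = function(conc) effect_logit(conc, coefs[["alpha"]], coefs[["beta"]]),
    fivepl  = function(conc) fivepl_eval_internal(conc, internal),
    abort(sprintf("unknown family '%s'", family))
  )
}

fit_monotone <- function(conc, effect, family) {
  x <- lg(conc)
  y <- effect
  y_clip <- pmin(pmax(y, 0.05), 99.95)
  w <- if (family == "weibull") log(-log(1 - y_clip / 100)) else stats::qlogis(y_clip / 100)
  st <- stats::coef(stats::lm(w ~ x))
  form <- if (family == "weibull") {
    y ~ 100 * (1 - exp(-exp(a + b * x)))
  } else {
    y ~ 100 / (1 + exp(-a - b * x))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = data.frame(x = x, y = y),
      start = list(a = unname(st[1L]), b = unname(st[2L])),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    raw <- c(a = unname(cf[["a"]]), b = unname(cf[["b"]]))
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  } else {
    # rank-deficient gradient (e.g. a near-perfect transform start): polish
    # the linearised estimate by direct least squares
    curve <- if (family == "weibull") {
      function(p) 100 * (1 - exp(-exp(p[1L] + p[2L] * x)))
    } else {
      function(p) 100 / (1 + exp(-p[1L] - p[2L] * x))
    }
    opt <- stats::optim(unname(st), function(p) sum((y - curve(p))^2),
                        method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 500))
    raw <- c(a = opt$par[1L], b = opt$par[2L])
    vc <- NULL
  }
  list(coefs = c(alpha = unname(raw[["a"]]), beta = unname(raw[["b"]])),
       internal = NULL, raw = raw, vcov = vc)
}

fit_fivepl_internal <- function(conc, effect) {
  x <- lg(conc)
  y <- effect
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  m0 <- min(ys)
  i_min <- which.min(ys)
  # falling limb half-effect location: first crossing of m0/2
  below <- which(ys[seq_len(i_min)] <= m0 / 2)
  le1_0 <- if (length(below)) xs[below[1L]] else xs[max(1L, i_min - 1L)]
  # rising limb: crossing of 50 after the minimum
  upper <- which(ys >= 50 & seq_along(ys) > i_min)
  le2_0 <- if (length(upper)) xs[upper[1L]] else max(xs)
  dat <- data.frame(x = x, y = y)
  form <- y ~ m / (1 + 10^(-b1 * (x - le1))) + (100 - m) / (1 + 10^(-b2 * (x - le2)))
  try_starts <- list(
    list(m = m0, le1 = le1_0, b1 = 2, le2 = le2_0, b2 = 2),
    list(m = 1.5 * m0, le1 = le1_0 - 0.3, b1 = 1, le2 = le2_0 + 0.2, b2 = 3),
    list(m = m0, le1 = le1_0, b1 = 4, le2 = le2_0, b2 = 1)
  )
  best <- NULL
  for (st in try_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st,
                        lower = c(m = -400, le1 = min(x) - 5, b1 = 0.05,
                                  le2 = min(x) - 5, b2 = 0.05),
                        upper = c(m = -1e-6, le1 = max(x) + 5, b1 = 50,
                                  le2 = max(x) + 5, b2 = 50),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("J-shaped model fit failed to converge from all starting values.",
          class = "mixray_fit_error")
  }
  cf <- coef(best$fit)
  internal <- list(m = unname(cf[["m"]]), le1 = unname(cf[["le1"]]),
                   b1 = unname(cf[["b1"]]), le2 = unname(cf[["le2"]]),
                   b2 = unname(cf[["b2"]]))
  # re-express as the semantic parameter set
  mn <- fivepl_minimum(internal)
  e_min <- mn$e_min
  f <- function(u) fivepl_eval_internal(10^u, internal)
  eps_up <- tryCatch({
    hi <- internal$le2 + 2
    while (f(hi) < 50 && hi < internal$le2 + 40) hi <- hi + 2
    10^uniroot(function(u) f(u) - 50, c(mn$lg_ec_min, hi), tol = 1e-12)$root
  }, error = function(e) NA_real_)
  eps_dn <- tryCatch({
    lo <- mn$lg_ec_min - 2
    while (f(lo) < e_min / 2 && lo > mn$lg_ec_min - 40) lo <- lo - 2
    10^uniroot(function(u) f(u) - e_min / 2, c(lo, mn$lg_ec_min), tol = 1e-12)$root
  }, error = function(e) NA_real_)
  list(coefs = c(e_min = e_min, eps_dn = eps_dn, beta_dn = internal$b1,
                 eps_up = eps_up, beta_up = internal$b2),
       internal = internal, raw = coef(best$fit),
       vcov = tryCatch(stats::vcov(best$fit), error = function(e) NULL))
}

#' Fit a concentration-response curve
#'
#' Least-squares fit of a monotonic (Weibull or Logit) or J-shaped
#' (hormetic five-parameter logistic) concentration-response model to
#' effect data in percent. With `family = "auto"` the monotone family with
#' the lower RMSE is chosen, and the J-shaped model is selected instead
#' only when the data show a negative (stimulatory) dip that it fits
#' better.
#'
#' @param data Data frame with one row per (mean) observation.
#' @param family One of `"auto"`, `"weibull"`, `"logit"`, `"fivepl"`.
#' @param conc,effect Column names (strings) holding concentration (mol/L)
#'   and effect (percent).
#' @return An object of class `crc_fit` with the fitted family, semantic
#'   coefficients, fit statistics (`r_squared`, `rmse`), and a 95%
#'   confidence band for the fitted curve. Supports [predict()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_crc <- function(data, family = c("auto", "weibull", "logit", "fivepl"),
                    conc = "concentration", effect = "effect") {
  family <- match.arg(family)
  cc <- data[[conc]]
  ee <- data[[effect]]
  if (is.null(cc) || is.null(ee)) {
    abort(sprintf("columns '%s' and '%s' are required", conc, effect),
          class = "mixray_input_error")
  }
  keep <- is.finite(cc) & is.finite(ee)
  cc <- cc[keep]; ee <- ee[keep]
  check_positive(cc, conc)
  if (length(unique(cc)) < 6L) {
    abort("at least 6 distinct concentrations are required.",
          class = "mixray_input_error")
  }
  if (sd(ee) < .Machine$double.eps^0.5) {
    abort("effects are constant; concentration-response fit is degenerate.",
          class = "mixray_fit_error")
  }

  fit_one <- function(fam) {
    res <- tryCatch(
      if (fam == "fivepl") fit_fivepl_internal(cc, ee) else fit_monotone(cc, ee, fam),
      error = function(e) e)
    if (inherits(res, "error")) return(res)
    fun <- crc_curve_fun(fam, res$coefs, res$internal)
    fitted <- fun(cc)
    resid <- ee - fitted
    new_crc_fit(
      family = fam, coefs = res$coefs, internal = res$internal,
      raw = res$raw, vcov = res$vcov,
      data = tibble::tibble(concentration = cc, effect = ee),
      fitted = fitted,
      r_squared = 1 - sum(resid^2) / sum((ee - mean(ee))^2),
      rmse = sqrt(mean(resid^2))
    )
  }

  if (family != "auto") {
    out <- fit_one(family)
    if (inherits(out, "error")) {
      abort(sprintf("fit of family '%s' failed: %s", family, conditionMessage(out)),
            class = "mixray_fit_error")
    }
    return(out)
  }

  cands <- list(fit_one("weibull"), fit_one("logit"))
  cands <- cands[!vapply(cands, inherits, logical(1L), "error")]
  if (!length(cands)) {
    abort("both monotone families failed to fit.", class = "mixray_fit_error")
  }
  mono <- cands[[which.min(vapply(cands, function(f) f$rmse, numeric(1L)))]]
  if (min(ee) < 0) {
    jfit <- fit_one("fivepl")
    if (!inherits(jfit, "error") && jfit$rmse < mono$rmse) return(jfit)
  }
  mono
}

new_crc_fit <- function(family, coefs, internal, raw, vcov, data, fitted,
                        r_squared, rmse) {
  structure(
    list(family = family, coefs = coefs, internal = internal,
         data = data, fitted = fitted, residuals = data$effect - fitted,
         r_squared = r_squared, rmse = rmse, n = nrow(data),
         n_par = length(raw), vcov = vcov, nls_coef = raw),
    class = "crc_fit")
}

#' @export
print.crc_fit <- function(x, ...) {
  cat(sprintf("<crc_fit> family = %s, n = %d\n", x$family, x$n))
  print(round(x$coefs, 6))
  cat(sprintf("R^2 = %.6f, RMSE = %.4f%%\n", x$r_squared, x$rmse))
  invisible(x)
}

#' Evaluate a fitted concentration-response curve
#'
#' @param object A `crc_fit`.
#' @param newdata Data frame with a `concentration` column, or a numeric
#'   concentration vector.
#' @param interval `"none"` for point predictions, `"confidence"` to add a
#'   95% confidence band (delta method on the fitted parameters).
#' @param ... Unused.
#' @return A tibble with `concentration`, `effect` and, if requested,
#'   `ci_lo`/`ci_hi`.
#' @export
predict.crc_fit <- function(object, newdata = NULL,
                            interval = c("none", "confidence"), ...) {
  interval <- match.arg(interval)
  conc <- if (is.null(newdata)) {
    object$data$concentration
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata$concentration
  }
  fun <- crc_curve_fun(object$family, object$coefs, object$internal)
  out <- tibble::tibble(concentration = conc, effect = fun(conc))
  if (interval == "confidence") {
    band <- crc_ci_band(object, conc)
    out$ci_lo <- band$lo
    out$ci_hi <- band$hi
  }
  out
}

# pointwise 95% confidence band for the fitted mean curve, delta method on
# the raw optimiser parameters
crc_ci_band <- function(fit, conc) {
  eff <- predict(fit, conc)$effect
  if (is.null(fit$vcov) || any(!is.finite(fit$vcov))) {
    return(list(lo = eff, hi = eff))
  }
  par <- fit$nls_coef
  curve_at <- function(p, cc) {
    if (fit$family == "fivepl") {
      internal <- list(m = p[["m"]], le1 = p[["le1"]], b1 = p[["b1"]],
                       le2 = p[["le2"]], b2 = p[["b2"]])
      fivepl_eval_internal(cc, internal)
    } else if (fit$family == "weibull") {
      effect_weibull(cc, p[["a"]], p[["b"]])
    } else {
      effect_logit(cc, p[["a"]], p[["b"]])
    }
  }
  h <- pmax(abs(par), 1) * 1e-6
  J <- vapply(seq_along(par), function(j) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    (curve_at(up, conc) - curve_at(dn, conc)) / (2 * h[j])
  }, numeric(length(conc)))
  J <- matrix(J, nrow = length(conc))
  se <- sqrt(pmax(rowSums((J %*% fit$vcov) * J), 0))
  tq <- qt(0.975, max(fit$n - fit$n_par, 1L))
  list(lo = eff - tq * se, hi = eff + tq * se)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.crc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefs), estimate = unname(x$coefs))
}

#' @export
glance.crc_fit <- function(x, ...) {
  tibble::tibble(family = x$family, r_squared = x$r_squared,
                 rmse = x$rmse, nobs = x$n)
}

# ---------------------------------------------------------------------------
# inversion and hormesis characteristics

#' Effective concentration at a given effect level
#'
#' Inverts a fitted concentration-response curve: the concentration at
#' which the curve equals `x` percent. For monotone families this is the
#' closed-form inverse, defined for `x` in (0, 100). For the J-shaped
#' family the rising-branch root (above the curve minimum) is returned for
#' `x` in (0, 100); any `x <= 0` is outside the invertible range and yields
#' `NA` — this is the predictive blind zone that the concentration-addition
#' model inherits.
#'
#' @param fit A `crc_fit`.
#' @param x Effect level(s) in percent.
#' @return Numeric vector of concentrations; `NA` marks an undefined
#'   (blind-zone) level, never a silent extrapolation.
#' @export
invert_ecx <- function(fit, x) {
  vapply(x, function(xx) invert_ecx_one(fit, xx), numeric(1L))
}

invert_ecx_one <- function(fit, x) {
  if (!is.finite(x)) return(NA_real_)
  if (fit$family %in% c("weibull", "logit")) {
    if (x <= 0 || x >= 100) return(NA_real_)
    a <- fit$coefs[["alpha"]]; b <- fit$coefs[["beta"]]
    lgc <- if (fit$family == "weibull") {
      (log(-log(1 - x / 100)) - a) / b
    } else {
      (stats::qlogis(x / 100) - a) / b
    }
    return(10^lgc)
  }
  # fivepl: rising branch only
  fivepl_rising_root(fit$internal, x)
}

# concentration on the rising branch (above the curve minimum) where the
# J-shaped curve reaches effect x; NA outside (0, 100)
fivepl_rising_root <- function(internal, x) {
  if (!is.finite(x) || x <= 0 || x >= 100) return(NA_real_)
  mn <- fivepl_minimum(internal)
  f <- function(u) fivepl_eval_internal(10^u, internal) - x
  hi <- internal$le2 + 2
  while (f(hi) < 0 && hi < internal$le2 + 60) hi <- hi + 2
  if (f(mn$lg_ec_min) > 0) return(NA_real_)
  10^uniroot(f, c(mn$lg_ec_min, hi), tol = 1e-12)$root
}

#' Characteristic points of a J-shaped concentration-response curve
#'
#' @param fit A `crc_fit` of family `"fivepl"`.
#' @return A one-row tibble: `ec_min` (concentration of the minimum),
#'   `e_min` (minimum effect, percent), `zep` (zero effect point, the
#'   concentration above `ec_min` where the curve crosses zero).
#' @export
hormesis_characteristics <- function(fit) {
  if (!inherits(fit, "crc_fit") || fit$family != "fivepl") {
    abort("`fit` must be a crc_fit of family 'fivepl'.",
          class = "mixray_input_error")
  }
  internal <- fit$internal
  mn <- fivepl_minimum(internal)
  if (mn$e_min >= 0) {
    abort("curve never goes below zero; not hormetic as parameterised.",
          class = "mixray_parameter_error")
  }
  f <- function(u) fivepl_eval_internal(10^u, internal)
  hi <- internal$le2 + 2
  while (f(hi) < 0 && hi < internal$le2 + 60) hi <- hi + 2
  zep <- 10^uniroot(function(u) f(u), c(mn$lg_ec_min, hi), tol = 1e-14)$root
  tibble::tibble(ec_min = 10^mn$lg_ec_min, e_min = mn$e_min, zep = zep)
}
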