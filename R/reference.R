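#' Concentration-addition EC_x of a fixed-ratio mixture
#'
#' Toxic-unit summation: for a mixture applied at fixed concentration
#' fractions `p`, the mixture concentration producing effect x is
#' `EC_x,mix = 1 / sum(p_i / EC_x,i)`. If any component has no effective
#' concentration at x (e.g. a monotone component at a negative, hormetic
#' effect level), the level lies in the predictive blind zone of
#' concentration addition and the result is undefined.
#'
#' @param p Numeric vector of concentration fractions, summing to 1.
#' @param ecx Per-component effective concentrations at the target effect
#'   level; `NA` marks an undefined component level.
#' @return A one-row tibble: `ec_x_mix` (mol/L, `NA` when undefined) and
#'   `blind_zone` (logical).
#' @examples
#' ca_ecx_ray(c(0.5, 0.5), c(1, 3)) # 1.5
#' @export
ca_ecx_ray <- function(p, ecx) {
  if (abs(sum(p) - 1) > 1e-8) {
    abort("`p` must sum to 1.", class = "mixray_domain_error")
  }
  if (length(p) != length(ecx)) {
    abort("`p` and `ecx` must have the same length.",
          class = "mixray_input_error")
  }
  blind <- any(!is.finite(ecx))
  tibble::tibble(
    ec_x_mix = if (blind) NA_real_ else 1 / sum(p / ecx),
    blind_zone = blind
  )
}

#' Concentration-addition effect of a mixture at a given total concentration
#'
#' Solves the toxic-unit summation for the effect level x at which
#' `sum(p_i * c_total / EC_x,i(x)) = 1`, using the fitted single-compound
#' curves to supply EC_x,i. The search runs over the effect range on which
#' every component has a defined effective concentration; when no such
#' level balances the toxic units (a predictive blind zone, e.g. below the
#' zero-effect point of a hormetic component applied nearly alone) the
#' result is `NA`.
#'
#' @param p Concentration fractions, summing to 1.
#' @param c_total Total mixture concentration(s), mol/L. Vectorised.
#' @param fits List of `crc_fit` objects, one per component (same order
#'   as `p`).
#' @param tol Bisection tolerance on the effect level (percent scale).
#' @return Numeric vector of effects in percent; `NA` marks a blind zone.
#' @export
ca_effect_at <- function(p, c_total, fits, tol = 1e-8) {
  if (abs(sum(p) - 1) > 1e-8) {
    abort("`p` must sum to 1.", class = "mixray_domain_error")
  }
  check_positive(c_total, "c_total")
  vapply(c_total, function(ct) ca_effect_one(p, ct, fits, tol), numeric(1L))
}

ca_effect_one <- function(p, ct, fits, tol) {
  tu_excess <- function(x) {
    ec <- vapply(fits, function(f) invert_ecx_one(f, x), numeric(1L))
    if (any(!is.finite(ec))) return(NA_real_)
    sum(p * ct / ec) - 1
  }
  lo <- 1e-6
  hi <- 100 - 1e-6
  g_lo <- tu_excess(lo)
  g_hi <- tu_excess(hi)
  if (!is.finite(g_lo) || !is.finite(g_hi)) return(NA_real_)
  if (g_hi > 0) return(hi)     # toxic units exceed 1 even at ~100% effect
  if (g_lo < 0) return(NA_real_) # below the attainable additive range
  uniroot(tu_excess, c(lo, hi), tol = tol)$root
}

#' Independent-action effect of a mixture
#'
#' `E = 1 - prod(1 - E_i)` on the fractional effect scale. Negative
#' (hormetic) component effects are accepted arithmetically but flagged
#' with a warning, since independent action loses its probabilistic
#' interpretation there.
#'
#' @param effects Per-component effects as fractions (effect% / 100).
#' @return Combined effect as a fraction.
#' @examples
#' ia_effect(c(0.5, 0.5)) # 0.75
#' @export
ia_effect <- function(effects) {
  if (any(!is.finite(effects))) {
    abort("`effects` must be finite fractions.", class = "mixray_domain_error")
  }
  if (any(effects < 0)) {
    warn(paste("negative (hormetic) component effects supplied to",
               "independent action; the model's conceptual framework does",
               "not cover stimulation."),
         class = "mixray_hormesis_warning")
  }
  1 - prod(1 - effects)
}

#' Effect residual ratio and interaction call
#'
#' Quantifies the deviation of the observed mixture effect from an
#' additive-reference prediction, relative to the 95% confidence interval
#' of the observation. When the prediction lies inside the CI the mixture
#' is additive and ERR = 0; otherwise ERR = 100 (E_CI - E_prd) / E_prd,
#' where E_CI is the CI limit nearer the prediction (upper limit under
#' antagonism, lower under synergism). ERR > 0 is synergism, ERR < 0
#' antagonism.
#'
#' @param e_ci Effect at the relevant CI limit, percent. Ignored when
#'   `inside_ci` is `TRUE`.
#' @param e_prd Additive-reference predicted effect, percent.
#' @param inside_ci Logical: does the prediction fall inside the CI?
#' @param normalize Denominator convention: `"prediction"` (default)
#'   divides by E_prd; `"hundred"` divides by 100.
#' @return A tibble with `err` (percent) and `call` (one of `"synergism"`,
#'   `"additive"`, `"antagonism"`).
#' @examples
#' err_statistic(40, 50, inside_ci = FALSE) # -20%, antagonism
#' @export
err_statistic <- function(e_ci, e_prd, inside_ci,
                          normalize = c("prediction", "hundred")) {
  normalize <- match.arg(normalize)
  n <- max(length(e_ci), length(e_prd), length(inside_ci))
  e_ci <- rep_len(e_ci, n)
  e_prd <- rep_len(e_prd, n)
  inside_ci <- rep_len(inside_ci, n)
  err <- numeric(n)
  out <- !inside_ci
  if (any(out)) {
    if (normalize == "prediction" && any(abs(e_prd[out]) < 1e-12)) {
      abort("E_prd is zero outside the CI; the effect residual ratio is undefined.",
            class = "mixray_domain_error")
    }
    denom <- if (normalize == "prediction") e_prd[out] else 100
    err[out] <- 100 * (e_ci[out] - e_prd[out]) / denom
  }
  tibble::tibble(
    err = err,
    call = dplyr::case_when(err > 0 ~ "synergism",
                            err < 0 ~ "antagonism",
                            TRUE ~ "additive")
  )
}

#' Interaction grid for a binary mixture system
#'
#' For each (ray, exposure time, effect level), fits the single-compound
#' and ray concentration-response curves, finds the ray concentration at
#' which the observed ray reaches the effect level, computes the
#' concentration-addition prediction at that concentration, and classifies
#' the interaction by CI overlap and the effect residual ratio. Observed
#' 95% CI bounds are interpolated between tested concentrations on the
#' lg-concentration scale.
#'
#' @param data Tidy dataset for one system: columns `id`, `role`
#'   (`"single"`/`"ray"`), `p_a`, `p_b`, `time_h`, `conc_total`, `effect`,
#'   `ci_lo`, `ci_hi` (as produced by [simulate_mixture_system()] or
#'   [read_toxicity_table()]).
#' @param effect_levels Effect levels in percent (default 10-80 by 10).
#' @param times Exposure times to analyse (default: all in `data`).
#' @param normalize ERR denominator convention, see [err_statistic()].
#' @return A tibble with one row per (ray, time, level): the CA-predicted
#'   effect, the observed CI, `err`, `call`, and a `note` marking blind
#'   zones or levels outside the tested range.
#' @export
interaction_table <- function(data, effect_levels = seq(10, 80, by = 10),
                              times = NULL,
                              normalize = c("prediction", "hundred")) {
  normalize <- match.arg(normalize)
  times <- times %||% sort(unique(data$time_h))
  purrr::map_dfr(times, function(tt) {
    dt <- dplyr::filter(data, .data$time_h == tt)
    singles <- dplyr::filter(dt, .data$role == "single")
    fit_a <- fit_crc(dplyr::filter(singles, .data$p_a == 1),
                     conc = "conc_total", effect = "effect")
    fit_b <- fit_crc(dplyr::filter(singles, .data$p_b == 1),
                     conc = "conc_total", effect = "effect")
    rays <- dplyr::filter(dt, .data$role == "ray")
    purrr::map_dfr(split(rays, rays$id), function(rr) {
      ray_fit <- fit_crc(rr, conc = "conc_total", effect = "effect")
      p <- c(rr$p_a[1L], rr$p_b[1L])
      purrr::map_dfr(effect_levels, function(x) {
        interaction_cell(rr, ray_fit, p, x, tt, list(fit_a, fit_b), normalize)
      })
    })
  })
}

interaction_cell <- function(rr, ray_fit, p, x, tt, fits, normalize) {
  base <- tibble::tibble(ray = rr$id[1L], time_h = tt, effect_level = x,
                         conc_total = NA_real_, e_prd = NA_real_,
                         ci_lo = NA_real_, ci_hi = NA_real_,
                         err = NA_real_, call = NA_character_, note = "")
  c_x <- invert_ecx_one(ray_fit, x)
  if (!is.finite(c_x)) {
    base$note <- "unattainable"
    return(base)
  }
  base$conc_total <- c_x
  e_prd <- ca_effect_one(p, c_x, fits, tol = 1e-8)
  if (!is.finite(e_prd)) {
    base$note <- "blind_zone"
    return(base)
  }
  base$e_prd <- e_prd
  lgc <- lg(rr$conc_total)
  if (lg(c_x) < min(lgc) || lg(c_x) > max(lgc)) {
    base$note <- "outside_tested_range"
    return(base)
  }
  lo <- stats::approx(lgc, rr$ci_lo, xout = lg(c_x), ties = mean)$y
  hi <- stats::approx(lgc, rr$ci_hi, xout = lg(c_x), ties = mean)$y
  base$ci_lo <- lo
  base$ci_hi <- hi
  inside <- e_prd >= lo && e_prd <= hi
  e_ci <- if (e_prd > hi) hi else lo
  es <- err_statistic(e_ci, e_prd, inside, normalize = normalize)
  base$err <- es$err
  base$call <- es$call
  base
}

#' Render an interaction grid in the wide ray-by-time layout
#'
#' Additive cells (and blind-zone / unattainable cells, which carry their
#' note) are rendered as an em dash, non-additive cells as the ERR value.
#'
#' @param grid Output of [interaction_table()].
#' @param digits Digits for ERR values.
#' @return A tibble with rows (ray, effect level) and one column per
#'   exposure time.
#' @export
format_interaction_grid <- function(grid, digits = 2) {
  grid$cell <- dplyr::case_when(
    is.na(grid$call) ~ "—",
    grid$call == "additive" ~ "—",
    TRUE ~ formatC(grid$err, format = "f", digits = digits)
  )
  tidyr::pivot_wider(
    dplyr::select(grid, "ray", "effect_level", "time_h", "cell"),
    names_from = "time_h", values_from = "cell", names_prefix = "t_"
  )
}
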