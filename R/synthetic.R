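# Synthetic binary-mixture assay generator.
#
# Emulates the structure of a time-dependent microplate bioluminescence-
# inhibition experiment: two single compounds and five EquRay mixture rays,
# each over a 12-point geometric dilution series, read at seven exposure
# times with replicate wells. The true mixture surface is the concentration-
# addition solution with an optional multiplicative toxic-unit deviation
# lambda(ray, effect level, time): lambda = 1 is additive, lambda > 1
# antagonistic, lambda < 1 synergistic. Replicate observations add Gaussian
# noise on the percent-effect scale; observed 95% CIs are replicate
# t-intervals.

#' Monotone Weibull component for the synthetic generator
#'
#' @param ec50 Median effective concentration (mol/L), a number or a
#'   function of exposure time (h) for time-dependent toxicity.
#' @param beta Slope on the lg-concentration scale (number or function of
#'   time).
#' @return A component generator: a function of time returning the true
#'   curve, its inverse, and the parameter vector.
#' @export
component_weibull <- function(ec50, beta = 2) {
  force(ec50); force(beta)
  function(time) {
    e <- if (is.function(ec50)) ec50(time) else ec50
    b <- if (is.function(beta)) beta(time) else beta
    a <- log(log(2)) - b * lg(e)
    list(family = "weibull",
         params = c(alpha = a, beta = b),
         fun = function(conc) effect_weibull(conc, a, b),
         ecx = function(x) {
           if (!is.finite(x) || x <= 0 || x >= 100) return(NA_real_)
           10^((log(-log(1 - x / 100)) - a) / b)
         })
  }
}

#' Monotone Logit component for the synthetic generator
#'
#' @inheritParams component_weibull
#' @return A component generator (see [component_weibull()]).
#' @export
component_logit <- function(ec50, beta = 4) {
  force(ec50); force(beta)
  function(time) {
    e <- if (is.function(ec50)) ec50(time) else ec50
    b <- if (is.function(beta)) beta(time) else beta
    a <- -b * lg(e)
    list(family = "logit",
         params = c(alpha = a, beta = b),
         fun = function(conc) effect_logit(conc, a, b),
         ecx = function(x) {
           if (!is.finite(x) || x <= 0 || x >= 100) return(NA_real_)
           10^((stats::qlogis(x / 100) - a) / b)
         })
  }
}

#' Hormetic (J-shaped) component for the synthetic generator
#'
#' With `e_min_trend = TRUE` the magnitude of the stimulatory minimum
#' grows with exposure time (from half strength at the first time to full
#' strength at the last), mirroring hormesis that develops over exposure.
#'
#' @inheritParams fivepl_params
#' @param e_min_trend Logical; scale `e_min` with exposure time.
#' @param times Exposure times the trend is scaled over (h).
#' @return A component generator (see [component_weibull()]).
#' @export
component_fivepl <- function(e_min, eps_dn, beta_dn, eps_up, beta_up,
                             e_min_trend = FALSE,
                             times = c(0.25, 2, 4, 6, 8, 10, 12)) {
  force_all <- c(e_min, eps_dn, beta_dn, eps_up, beta_up)
  function(time) {
    em <- if (e_min_trend) {
      frac <- 0.5 + 0.5 * (time - min(times)) / (max(times) - min(times))
      e_min * frac
    } else {
      e_min
    }
    p <- fivepl_params(em, eps_dn, beta_dn, eps_up, beta_up)
    list(family = "fivepl",
         params = c(e_min = em, eps_dn = eps_dn, beta_dn = beta_dn,
                    eps_up = eps_up, beta_up = beta_up),
         fun = function(conc) fivepl_eval_internal(conc, p$internal),
         ecx = function(x) fivepl_rising_root(p$internal, x))
  }
}

# true effect of a fixed-ratio mixture point: the effect level x at which
# the lambda-inflated toxic units sum to lambda(x)
ray_effect_truth <- function(p, ct, comps, lam) {
  g <- function(x) {
    lv <- lam(x)
    if (!is.finite(lv) || lv <= 0) {
      abort("`lambda` must be finite and > 0.", class = "mixray_spec_error")
    }
    ec <- vapply(comps, function(cm) cm$ecx(x), numeric(1L))
    if (any(!is.finite(ec))) return(NA_real_)
    sum(p * ct / ec) - lv
  }
  lo <- 1e-6; hi <- 100 - 1e-6
  g_lo <- g(lo); g_hi <- g(hi)
  if (!is.finite(g_lo) || !is.finite(g_hi)) return(NA_real_)
  if (g_hi > 0) return(NA_real_) # saturated: no effect level in range
  if (g_lo < 0) return(NA_real_)
  uniroot(g, c(lo, hi), tol = 1e-10)$root
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a complete binary-mixture toxicity dataset
#'
#' Generates singles and EquRay mixture rays over a geometric dilution
#' series at multiple exposure times, with replicate noise and observed
#' 95% confidence intervals, in the tidy schema read by
#' [read_toxicity_table()] and consumed by the fitting, interpolation and
#' validation functions.
#'
#' @param component_a,component_b Component generators, e.g.
#'   [component_weibull()] or [component_fivepl()].
#' @param times Exposure times in hours (default the 7-point series
#'   0.25-12 h).
#' @param n_rays,n_conc Number of mixture rays (default 5) and dilution
#'   levels (default 12).
#' @param dilution_factor Geometric dilution factor (default 0.7).
#' @param lambda Toxic-unit deviation: `NULL` for strict additivity, or a
#'   function `(ray, x, time) -> multiplier` (> 0; < 1 synergism, > 1
#'   antagonism).
#' @param noise_sd Replicate noise standard deviation, percent effect
#'   (default 5).
#' @param n_replicates Replicate wells per concentration (default 3).
#' @param anchor_time Exposure time whose EC50s anchor the EquRay ratios
#'   (default the last time).
#' @param seed Integer seed for reproducibility (the RNG state is
#'   restored afterwards).
#' @return A tibble with one row per (point, time): `id`, `role`, `p_a`,
#'   `p_b`, `level`, `conc_total`, `conc_a`, `conc_b`, `time_h`,
#'   `effect_true`, replicate columns `rep1..repN`, `effect` (replicate
#'   mean), `ci_lo`, `ci_hi`.
#' @export
simulate_mixture_system <- function(component_a = component_weibull(1e-3, 2),
                                    component_b = component_weibull(1e-4, 3),
                                    times = c(0.25, 2, 4, 6, 8, 10, 12),
                                    n_rays = 5L, n_conc = 12L,
                                    dilution_factor = 0.7,
                                    lambda = NULL,
                                    noise_sd = 5, n_replicates = 3L,
                                    anchor_time = max(times),
                                    seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "mixray_spec_error")
  comps_anchor <- list(component_a(anchor_time), component_b(anchor_time))
  ec50 <- vapply(comps_anchor, function(cm) cm$ecx(50), numeric(1L))
  if (any(!is.finite(ec50))) {
    abort("components must reach 50% effect at the anchor time.",
          class = "mixray_spec_error")
  }
  design <- equray_design(ec50[1L], ec50[2L], n_rays = n_rays,
                          n_conc = n_conc, factor = dilution_factor)
  design$id <- design$ray
  design$role <- "ray"
  singles <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(
      id = c("A", "B")[i], role = "single",
      p_a = c(1, 0)[i], p_b = c(0, 1)[i],
      level = seq_len(n_conc),
      conc_total = dilution_series(4 * ec50[i], n = n_conc,
                                   factor = dilution_factor))
  })
  singles$conc_a <- singles$p_a * singles$conc_total
  singles$conc_b <- singles$p_b * singles$conc_total
  layout <- dplyr::bind_rows(
    singles,
    dplyr::select(design, "id", "role", "p_a", "p_b", "level",
                  "conc_total", "conc_a", "conc_b"))

  grid <- tidyr::crossing(layout, time_h = times)
  comp_cache <- lapply(times, function(tt) list(component_a(tt), component_b(tt)))
  names(comp_cache) <- as.character(times)

  grid$effect_true <- purrr::pmap_dbl(
    list(grid$id, grid$role, grid$p_a, grid$conc_total, grid$time_h),
    function(id, role, p_a, ct, tt) {
      comps <- comp_cache[[as.character(tt)]]
      if (role == "single") {
        if (p_a == 1) comps[[1L]]$fun(ct) else comps[[2L]]$fun(ct)
      } else {
        lam <- if (is.null(lambda)) {
          function(x) 1
        } else {
          function(x) lambda(id, x, tt)
        }
        ray_effect_truth(c(p_a, 1 - p_a), ct, comps, lam)
      }
    })
  if (any(!is.finite(grid$effect_true)) ||
      any(abs(grid$effect_true) >= 100)) {
    abort("true effects fall outside (-100, 100); check lambda and components.",
          class = "mixray_spec_error")
  }

  with_seed(seed, {
    reps <- matrix(rnorm(nrow(grid) * n_replicates, mean = grid$effect_true,
                         sd = noise_sd),
                   nrow = nrow(grid))
    colnames(reps) <- paste0("rep", seq_len(n_replicates))
    grid <- dplyr::bind_cols(grid, tibble::as_tibble(reps))
    grid$effect <- rowMeans(reps)
    if (n_replicates > 1L) {
      se <- apply(reps, 1L, sd) / sqrt(n_replicates)
      tq <- qt(0.975, n_replicates - 1L)
      grid$ci_lo <- grid$effect - tq * se
      grid$ci_hi <- grid$effect + tq * se
    } else {
      grid$ci_lo <- grid$effect
      grid$ci_hi <- grid$effect
    }
    grid
  })
}

#' Simulate a hormetic single-compound dataset
#'
#' Single-compound data from the J-shaped response model, with an optional
#' exposure-time trend that deepens the stimulatory minimum over time.
#'
#' @inheritParams fivepl_params
#' @inheritParams simulate_mixture_system
#' @param e_min_trend Logical; let `|e_min|` grow with exposure time.
#' @return A tibble in the same schema as [simulate_mixture_system()]
#'   (single compound only, `id = "B"`).
#' @export
generate_hormetic_component <- function(e_min = -20, eps_dn = 1e-5,
                                        beta_dn = 1.5, eps_up = 1e-3,
                                        beta_up = 2,
                                        times = c(0.25, 2, 4, 6, 8, 10, 12),
                                        e_min_trend = FALSE,
                                        n_conc = 12L, dilution_factor = 0.7,
                                        noise_sd = 5, n_replicates = 3L,
                                        seed = NULL) {
  gen <- component_fivepl(e_min, eps_dn, beta_dn, eps_up, beta_up,
                          e_min_trend = e_min_trend, times = times)
  conc <- dilution_series(4 * eps_up, n = n_conc, factor = dilution_factor)
  grid <- tidyr::crossing(
    tibble::tibble(id = "B", role = "single", p_a = 0, p_b = 1,
                   level = seq_len(n_conc), conc_total = conc),
    time_h = times)
  grid$conc_a <- 0
  grid$conc_b <- grid$conc_total
  grid$effect_true <- purrr::map2_dbl(grid$conc_total, grid$time_h,
                                      function(ct, tt) gen(tt)$fun(ct))
  with_seed(seed, {
    reps <- matrix(rnorm(nrow(grid) * n_replicates, mean = grid$effect_true,
                         sd = noise_sd), nrow = nrow(grid))
    colnames(reps) <- paste0("rep", seq_len(n_replicates))
    grid <- dplyr::bind_cols(grid, tibble::as_tibble(reps))
    grid$effect <- rowMeans(reps)
    if (n_replicates > 1L) {
      se <- apply(reps, 1L, sd) / sqrt(n_replicates)
      tq <- qt(0.975, n_replicates - 1L)
      grid$ci_lo <- grid$effect - tq * se
      grid$ci_hi <- grid$effect + tq * se
    } else {
      grid$ci_lo <- grid$effect
      grid$ci_hi <- grid$effect
    }
    grid
  })
}

#' Generate-fit-validate parameter recovery report
#'
#' Runs the full pipeline on a small grid of generated scenarios
#' (noise-free vs noisy, additive vs synergistic ray, monotone vs hormetic
#' component) and reports recovery of the single-compound curve parameters
#' plus cross-validated accuracy rates.
#'
#' @param seed Master seed.
#' @param times Exposure times used for the scenario systems (a subset
#'   keeps the report quick).
#' @return A tibble with `scenario`, `metric`, `value`.
#' @export
parameter_recovery_suite <- function(seed = 1L, times = c(2, 6, 12)) {
  out <- list()
  true_a <- c(alpha = log(log(2)) - 2 * lg(1e-3), beta = 2)

  # 1. noise-free parameter recovery
  sys0 <- simulate_mixture_system(times = times, noise_sd = 0,
                                  n_replicates = 1L, seed = seed)
  fits <- lapply(times, function(tt) {
    fit_crc(dplyr::filter(sys0, .data$id == "A", .data$time_h == tt),
            family = "weibull", conc = "conc_total", effect = "effect")
  })
  bias <- max(vapply(fits, function(f) max(abs(f$coefs - true_a)), numeric(1L)))
  out$noise_free <- tibble::tibble(scenario = "additive_noise_free",
                                   metric = "max_param_abs_error",
                                   value = bias)

  # 2. noisy additive system: cross-validated accuracy
  sys5 <- simulate_mixture_system(times = times, noise_sd = 5, seed = seed + 1L)
  cv <- lmocv(sys5, n_repeats = 5L, seed = seed + 2L)
  gl <- glance(cv)
  out$noisy <- tibble::tibble(
    scenario = "additive_noise5",
    metric = paste0("ar_", gl$method),
    value = gl$ar)

  # 3. hormetic component: the interpolator predicts in CA's blind zone
  sysh <- simulate_mixture_system(
    component_b = component_fivepl(-20, 1e-5, 1.5, 1e-3, 2),
    times = times, noise_sd = 2, seed = seed + 3L)
  tt <- times[length(times)]
  fit_a <- fit_crc(dplyr::filter(sysh, .data$id == "A", .data$time_h == tt),
                   conc = "conc_total", effect = "effect")
  fit_b <- fit_crc(dplyr::filter(sysh, .data$id == "B", .data$time_h == tt),
                   conc = "conc_total", effect = "effect")
  # CA has no effective concentration at a stimulatory (negative) level
  # because the monotone partner never reaches it
  ca <- ca_ecx_ray(c(0.5, 0.5),
                   c(invert_ecx(fit_a, -5), invert_ecx(fit_b, -5)))
  # ... but the interpolator still predicts on the hormetic axis, inside
  # the stimulation zone
  q <- tibble::tibble(conc_a = 0, conc_b = 1.5e-4, time_h = tt)
  pred <- predict_toxicity(dplyr::filter(sysh, .data$time_h == tt), q)
  out$hormetic <- tibble::tibble(
    scenario = "hormetic_blind_zone",
    metric = c("ca_defined", "interp_predicts", "interp_prediction_negative"),
    value = c(as.numeric(!ca$blind_zone),
              as.numeric(is.finite(pred$pred_neiip)),
              as.numeric(is.finite(pred$pred_neiip) && pred$pred_neiip < 0)))

  dplyr::bind_rows(out)
}
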