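#' EquRay fixed-ratio mixture ratios
#'
#' Direct equipartition ray design for a binary mixture: ray k of n has
#' toxic-unit proportions (n + 1 - k) : k anchored on the two components'
#' EC50s, so the middle ray of five is equitoxic (1:1 in toxic units). The
#' concentration ratio of component A in ray k is
#' `p_a = (n+1-k) EC50_a / ((n+1-k) EC50_a + k EC50_b)`.
#'
#' @param ec50_a,ec50_b Median effective concentrations (mol/L) of the two
#'   components, used as toxic-unit anchors.
#' @param n_rays Number of rays (default 5, giving R1..R5).
#' @return A tibble with one row per ray: `ray`, toxic-unit weights
#'   `tu_a`/`tu_b`, and concentration fractions `p_a`/`p_b` (summing to 1).
#' @examples
#' equray_ratios(0.02, 0.04) # R3 has p_a = 1/3
#' @export
equray_ratios <- function(ec50_a, ec50_b, n_rays = 5L) {
  check_positive(c(ec50_a, ec50_b), "ec50_a/ec50_b")
  if (n_rays < 1L) abort("`n_rays` must be >= 1.", class = "mixray_domain_error")
  k <- seq_len(n_rays)
  wa <- n_rays + 1L - k
  wb <- k
  p_a <- wa * ec50_a / (wa * ec50_a + wb * ec50_b)
  tibble::tibble(ray = paste0("R", k), tu_a = wa, tu_b = wb,
                 p_a = p_a, p_b = 1 - p_a)
}

#' Geometric dilution series
#'
#' The 12-point concentration gradient used for each single compound and
#' mixture ray: a geometric series from the stock concentration downward.
#'
#' @param stock Highest (stock) concentration, mol/L.
#' @param n Number of concentrations (default 12).
#' @param factor Dilution factor between consecutive levels, in (0, 1)
#'   (default 0.7).
#' @return Numeric vector of length `n`, strictly decreasing from `stock`.
#' @examples
#' dilution_series(1, n = 3, factor = 0.5) # 1, 0.5, 0.25
#' @export
dilution_series <- function(stock, n = 12L, factor = 0.7) {
  check_positive(stock, "stock")
  if (!is.finite(factor) || factor <= 0 || factor >= 1) {
    abort("`factor` must be strictly between 0 and 1.",
          class = "mixray_domain_error")
  }
  if (n < 1L) abort("`n` must be >= 1.", class = "mixray_domain_error")
  stock * factor^(seq_len(n) - 1L)
}

#' Full EquRay design table for a binary mixture system
#'
#' Combines [equray_ratios()] with a [dilution_series()] per ray (and,
#' optionally, per single compound) into the concentration layout of one
#' binary mixture experiment.
#'
#' @inheritParams equray_ratios
#' @param stocks Stock total concentration per ray: a single number reused
#'   for every ray, or a vector of length `n_rays`. Default anchors each
#'   ray's stock at 4x its additive (concentration-addition) EC50 proxy,
#'   `4 / (p_a/ec50_a + p_b/ec50_b)`, so the series spans the effect range.
#' @param n_conc Number of dilution levels per ray (default 12).
#' @param factor Dilution factor (default 0.7).
#' @return A tibble with one row per (ray, level): `ray`, `p_a`, `p_b`,
#'   `level`, `conc_total`, `conc_a`, `conc_b`.
#' @export
equray_design <- function(ec50_a, ec50_b, n_rays = 5L, stocks = NULL,
                          n_conc = 12L, factor = 0.7) {
  ratios <- equray_ratios(ec50_a, ec50_b, n_rays)
  if (is.null(stocks)) {
    stocks <- 4 / (ratios$p_a / ec50_a + ratios$p_b / ec50_b)
  } else if (length(stocks) == 1L) {
    stocks <- rep(stocks, n_rays)
  }
  if (length(stocks) != n_rays) {
    abort("`stocks` must have length 1 or `n_rays`.",
          class = "mixray_input_error")
  }
  ratios$stock <- stocks
  out <- tidyr::crossing(ratios, level = seq_len(n_conc))
  out$conc_total <- out$stock * factor^(out$level - 1L)
  out$conc_a <- out$p_a * out$conc_total
  out$conc_b <- out$p_b * out$conc_total
  dplyr::select(out, "ray", "p_a", "p_b", "level",
                "conc_total", "conc_a", "conc_b")
}
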