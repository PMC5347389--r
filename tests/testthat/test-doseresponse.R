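test_that("monotone response functions match their closed forms", {
  expect_equal(effect_weibull(1, 0, 1), 100 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(effect_logit(1, 0, 3), 50)
  expect_equal(effect_logit(10, 1, 2), 100 / (1 + exp(-3)), tolerance = 1e-12)
  # median by construction: alpha + beta lg c = ln ln 2 at c*
  beta <- 1.7
  c_star <- 3.2e-4
  alpha <- log(log(2)) - beta * lg(3.2e-4)
  expect_equal(effect_weibull(c_star, alpha, beta), 50, tolerance = 1e-10)
  # limits and monotonicity
  expect_lt(effect_weibull(1e-12, 0, 1), 1e-3)
  expect_gt(effect_logit(1e12, 0, 1), 100 - 1e-3)
  cgrid <- 10^seq(-6, 2, length.out = 50)
  expect_true(all(diff(effect_weibull(cgrid, 0.5, 1.2)) > 0))
  expect_error(effect_weibull(-1, 0, 1), class = "mixray_domain_error")
  expect_error(effect_logit(0, 0, 1), class = "mixray_domain_error")
})

test_that("J-shaped model honours all printed parameter semantics", {
  set.seed(41)
  for (i in 1:12) {
    e_min <- runif(1, -40, -5)
    eps_dn <- 10^runif(1, -6, -4.5)
    eps_up <- eps_dn * 10^runif(1, 1.2, 2.5)
    beta_dn <- runif(1, 0.8, 3)
    beta_up <- runif(1, 1, 4)
    p <- fivepl_params(e_min, eps_dn, beta_dn, eps_up, beta_up)
    expect_equal(effect_fivepl(eps_up, p), 50, tolerance = 1e-6)
    expect_equal(effect_fivepl(eps_dn, p), e_min / 2, tolerance = 1e-6)
    grid <- 10^seq(lg(eps_dn) - 4, lg(eps_up) + 2, length.out = 2000)
    expect_equal(min(effect_fivepl(grid, p)), e_min, tolerance = 1e-4)
    expect_lt(effect_fivepl(eps_dn * 1e-4, p), 0.5 + abs(e_min) * 0.02)
    expect_gt(effect_fivepl(eps_up * 1e4, p), 99)
    # one dominant interior minimum: decreasing to the argmin and rising
    # after it, up to sub-0.05% ripples in the power-law tails of the
    # double-logistic form
    vals <- effect_fivepl(grid, p)
    i_min <- which.min(vals)
    expect_true(i_min > 1L && i_min < length(vals))
    expect_lt(max(diff(vals[seq_len(i_min)])), 0.05)
    expect_gt(min(diff(vals[i_min:length(vals)])), -0.05)
  }
  expect_error(fivepl_params(10, 1e-5, 1, 1e-3, 1),
               class = "mixray_parameter_error")
  expect_error(fivepl_params(-10, 1e-3, 1, 1e-5, 1),
               class = "mixray_parameter_error")
})

test_that("noise-free data are recovered exactly by fit_crc", {
  conc <- dilution_series(2e-2, 12, 0.65)
  for (fam in c("weibull", "logit")) {
    true <- c(alpha = 6.4, beta = 2.1)
    eff <- if (fam == "weibull") effect_weibull(conc, 6.4, 2.1)
           else effect_logit(conc, 6.4, 2.1)
    fit <- fit_crc(tibble::tibble(concentration = conc, effect = eff), fam)
    expect_equal(unname(fit$coefs), unname(true), tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  p <- fivepl_params(-25, 2e-5, 1.8, 8e-4, 2.4)
  conc <- dilution_series(8e-3, 16, 0.55)
  dj <- tibble::tibble(concentration = conc, effect = effect_fivepl(conc, p))
  fj <- fit_crc(dj, "fivepl")
  expect_equal(fj$coefs[["e_min"]], -25, tolerance = 1e-4)
  expect_equal(fj$coefs[["eps_dn"]], 2e-5, tolerance = 1e-4)
  expect_equal(fj$coefs[["eps_up"]], 8e-4, tolerance = 1e-4)
  expect_equal(fj$coefs[["beta_dn"]], 1.8, tolerance = 1e-4)
  expect_equal(fj$coefs[["beta_up"]], 2.4, tolerance = 1e-4)
  expect_equal(fj$r_squared, 1, tolerance = 1e-9)
})

test_that("family selection and degenerate inputs behave", {
  conc <- dilution_series(1e-2, 12, 0.6)
  mono <- tibble::tibble(concentration = conc,
                         effect = effect_logit(conc, 7, 2.2))
  expect_true(fit_crc(mono, "auto")$family %in% c("weibull", "logit"))
  p <- fivepl_params(-20, 1e-5, 1.5, 1e-3, 2)
  concj <- dilution_series(5e-3, 14, 0.5)
  horm <- tibble::tibble(concentration = concj,
                         effect = effect_fivepl(concj, p))
  expect_identical(fit_crc(horm, "auto")$family, "fivepl")
  expect_error(
    fit_crc(tibble::tibble(concentration = conc, effect = rep(0, 12))),
    class = "mixray_fit_error")
  expect_error(
    fit_crc(tibble::tibble(concentration = conc[1:4],
                           effect = effect_logit(conc[1:4], 7, 2.2))),
    class = "mixray_input_error")
})

test_that("effective-concentration inversion round-trips and marks blind zones", {
  conc <- dilution_series(3e-2, 12, 0.6)
  fit <- fit_crc(tibble::tibble(concentration = conc,
                                effect = effect_weibull(conc, 5.5, 1.9)),
                 "weibull")
  # closed-form check: alpha = 0, beta = 1 gives EC50 = 10^(ln ln 2)
  conc0 <- dilution_series(10, 12, 0.55) # spans that EC50 (~0.43)
  f0 <- fit_crc(tibble::tibble(concentration = conc0,
                               effect = effect_weibull(conc0, 0, 1)), "weibull")
  expect_equal(invert_ecx(f0, 50), 10^log(log(2)), tolerance = 1e-6)
  # round trip over a concentration grid
  grid <- 10^seq(lg(min(conc)), lg(max(conc)), length.out = 30)
  eff <- predict(fit, grid)$effect
  expect_equal(invert_ecx(fit, eff), grid, tolerance = 1e-8)
  expect_true(is.na(invert_ecx(fit, -5)))
  expect_true(is.na(invert_ecx(fit, 100)))

  p <- fivepl_params(-10, 1e-5, 1.5, 1e-3, 2)
  concj <- dilution_series(5e-3, 14, 0.5)
  fj <- fit_crc(tibble::tibble(concentration = concj,
                               effect = effect_fivepl(concj, p)), "fivepl")
  expect_equal(invert_ecx(fj, 50), 1e-3, tolerance = 1e-4)
  expect_true(is.na(invert_ecx(fj, -30))) # below attainable minimum
  expect_true(is.na(invert_ecx(fj, -5)))  # stimulation zone: blind for CA
  # rising-branch round trip
  cg <- 10^seq(lg(invert_ecx(fj, 1)), lg(invert_ecx(fj, 95)), length.out = 20)
  expect_equal(invert_ecx(fj, predict(fj, cg)$effect), cg, tolerance = 1e-6)
})

test_that("hormesis characteristic points are ordered and definitional", {
  p <- fivepl_params(-18, 3e-5, 1.2, 6e-4, 2.5)
  conc <- dilution_series(4e-3, 16, 0.55)
  fit <- fit_crc(tibble::tibble(concentration = conc,
                                effect = effect_fivepl(conc, p)), "fivepl")
  hc <- hormesis_characteristics(fit)
  expect_equal(predict(fit, hc$ec_min)$effect, hc$e_min, tolerance = 1e-8)
  expect_equal(predict(fit, hc$zep)$effect, 0, tolerance = 1e-8)
  expect_lt(hc$ec_min, hc$zep)
  expect_lt(hc$zep, invert_ecx(fit, 50))
  expect_equal(hc$e_min, -18, tolerance = 1e-3)
  mono <- fit_crc(tibble::tibble(concentration = conc,
                                 effect = effect_logit(conc, 8, 2.5)), "logit")
  expect_error(hormesis_characteristics(mono), class = "mixray_input_error")
})

test_that("crc_fit supports the tidyverse verbs", {
  conc <- dilution_series(1e-2, 12, 0.6)
  fit <- fit_crc(tibble::tibble(concentration = conc,
                                effect = effect_weibull(conc, 6, 2) +
                                  rnorm(12, 0, 1)), "weibull")
  td <- generics::tidy(fit)
  expect_identical(td$term, c("alpha", "beta"))
  gl <- generics::glance(fit)
  expect_identical(gl$family, "weibull")
  expect_lte(gl$r_squared, 1)
  pr <- predict(fit, conc, interval = "confidence")
  expect_true(all(pr$ci_lo <= pr$effect & pr$effect <= pr$ci_hi))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
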