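test_that("iodine-assay absorbance converts to specific activity", {
  zero <- absorbance_to_specific_activity(0, 1500, 5, 0.00485)
  expect_equal(zero$specific_activity, 0)

  # 0.5 AU x 1500 ug/AU over 5 min with 0.097 mg/ml x 0.05 ml = 0.00485 mg
  act <- absorbance_to_specific_activity(0.5, 1500, 5, 0.00485)
  expect_equal(act$specific_activity, 750 / 5 / 0.00485 / 1000, tolerance = 1e-12)
  expect_equal(round(act$specific_activity, 2), 30.93)
  expect_false(act$clipped)

  expect_warning(neg <- absorbance_to_specific_activity(-0.1, 1500, 5, 0.00485))
  expect_equal(neg$specific_activity, 0)
  expect_true(neg$clipped)

  expect_error(absorbance_to_specific_activity(0.5, 1500, 0, 0.00485),
               class = "gt_validation_error")
})

test_that("transglycosylation factors reproduce the printed activity table", {
  # maltotriose 27.4 over baseline 1.5 -> 18.27, printing as 18.3
  tf <- transglycosylation_factor(27.4, 1.5, with_sd = 2.3, without_sd = 0.2)
  expect_equal(tf$factor, 27.4 / 1.5, tolerance = 1e-12)
  expect_equal(round(tf$factor, 1), 18.3)
  expect_true(is.finite(tf$sd) && tf$sd > 0)

  # glucose 6.8 / 1.5 recomputes to 4.53; the printed 4.6 reflects rounding of
  # the unrounded raw activities, so agreement is to the last printed digit
  tf_glc <- transglycosylation_factor(6.8, 1.5)
  expect_equal(tf_glc$factor, 4.5333, tolerance = 1e-4)
  expect_lte(abs(round(tf_glc$factor, 1) - 4.6), 0.1)

  expect_equal(transglycosylation_factor(3.7, 3.7)$factor, 1)
  expect_error(transglycosylation_factor(5, 0), class = "gt_division_error")
})

test_that("table-wide transglycosylation factors use the no-acceptor baseline", {
  act <- tibble::tibble(
    condition = c("no acceptor", "glucose", "maltose", "maltotriose"),
    specific_activity = c(1.5, 6.8, 18.2, 27.4),
    sd = c(0.2, 0.3, 1.6, 2.3)
  )
  tf <- transglycosylation_factors(act)
  expect_equal(tf$condition, c("glucose", "maltose", "maltotriose"))
  expect_equal(round(tf$factor, 1), c(4.5, 12.1, 18.3))
  expect_error(transglycosylation_factors(dplyr::filter(act, condition != "no acceptor")),
               class = "gt_validation_error")
})

test_that("Lineweaver-Burk recovers noiseless Michaelis-Menten parameters", {
  # closed-form reciprocal algebra: KM = 2, Vmax = 10 -> slope 0.2, intercept 0.1
  s <- c(0.5, 1, 2, 4, 8)
  d <- tibble::tibble(concentration_mM = s, velocity = 10 * s / (2 + s))
  fit <- fit_lineweaver_burk(d)
  co <- stats::coef(fit$lm_fit)
  expect_equal(unname(co[1]), 0.1, tolerance = 1e-9)
  expect_equal(unname(co[2]), 0.2, tolerance = 1e-9)
  expect_equal(fit$KM, 2, tolerance = 1e-9)
  expect_equal(fit$Vmax, 10, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # constant velocity: saturation limit, KM -> 0
  flat <- tibble::tibble(concentration_mM = s, velocity = rep(7, 5))
  ffit <- fit_lineweaver_burk(flat)
  expect_equal(ffit$KM, 0, tolerance = 1e-12)
  expect_equal(ffit$Vmax, 7, tolerance = 1e-12)

  expect_error(fit_lineweaver_burk(d[1:2, ]), class = "gt_validation_error")
  bad <- tibble::tibble(concentration_mM = s, velocity = c(4, 3, 2, 1, 0.5))
  expect_error(fit_lineweaver_burk(bad), class = "gt_fit_failure_error")
})

test_that("parameter recovery is exact for any >= 3 point noiseless design", {
  set.seed(31)
  for (i in 1:20) {
    km <- runif(1, 0.2, 8); vmax <- runif(1, 100, 5000)
    s <- sort(runif(sample(3:8, 1), 0.1, 12))
    if (length(unique(s)) < 3) next
    d <- tibble::tibble(concentration_mM = s, velocity = vmax * s / (km + s))
    fit <- fit_lineweaver_burk(d)
    expect_equal(fit$KM, km, tolerance = 1e-3 * km)
    expect_equal(fit$Vmax, vmax, tolerance = 1e-3 * vmax)
  }
})

test_that("kcat conversion uses the molar enzyme concentration", {
  e_um <- enzyme_molar_concentration(0.097, 76002)
  expect_equal(e_um, 1.276, tolerance = 1e-3)
  expect_equal(vmax_to_kcat(e_um, 0.097, 76002), 1)        # Vmax = E -> kcat 1
  expect_equal(vmax_to_kcat(3363, 0.097, 76002), 2635, tolerance = 1e-3)
  expect_error(vmax_to_kcat(10, 0.097, 0), class = "gt_validation_error")
})

test_that("catalytic efficiencies reproduce the printed kinetic table", {
  expect_equal(round(efficiency_ratio(2635, 0.86)), 3064)
  expect_equal(round(efficiency_ratio(2008, 1.81)), 1109)
  # glucose row: recomputation gives 168.8 vs printed 168 (last-digit rounding)
  expect_lte(abs(round(efficiency_ratio(1141, 6.76)) - 168), 1)
  expect_equal(efficiency_ratio(0, 5), 0)
})

test_that("the direct nonlinear fit cross-checks the double-reciprocal route", {
  d <- gen_mm_dataset(1.81, 2008, noise_cv = 0.02, seed = 32)
  lb <- fit_lineweaver_burk(d, enzyme_concentration = 0.097, enzyme_molar_mass = 76002)
  nls_fit <- fit_michaelis_menten(d, enzyme_concentration = 0.097,
                                  enzyme_molar_mass = 76002)
  expect_equal(nls_fit$KM, lb$KM, tolerance = 0.2)
  expect_equal(nls_fit$kcat, lb$kcat, tolerance = 0.1 * lb$kcat)
})

test_that("tidy and glance summarise kinetic fits", {
  d <- gen_mm_dataset(0.86, 2635)
  fit <- fit_lineweaver_burk(d, enzyme_concentration = 0.097, enzyme_molar_mass = 76002)
  td <- tidy(fit)
  expect_equal(td$term, c("KM", "Vmax", "kcat", "efficiency"))
  expect_equal(td$estimate[1], 0.86, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$n, 6L)
  expect_equal(gl$r_squared, 1, tolerance = 1e-9)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
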