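#' Convert an iodine-assay absorbance change to specific activity
#'
#' The amylose-iodine assay reports activity as amylose hydrolysed per
#' minute per mg enzyme: one unit is 1 ug amylose hydrolysed per minute.
#' The absorbance decrease at 660 nm is converted through a calibration
#' slope (ug amylose per absorbance unit) and normalised by reaction time
#' and enzyme load; the result is reported in mg amylose min^-1 mg^-1.
#'
#' @param delta_a660 Absorbance decrease at 660 nm. Negative values are
#'   clipped to zero and flagged.
#' @param calibration_slope ug amylose per absorbance unit (> 0).
#' @param reaction_minutes Reaction time, minutes (> 0).
#' @param enzyme_mg Enzyme in the reaction, mg (> 0).
#' @param condition Label (acceptor name or "no acceptor").
#' @param acceptor_concentration Acceptor concentration, mM (optional).
#' @param sd Optional standard deviation on the same scale as the activity.
#' @return One-row tibble: `condition`, `acceptor_concentration`,
#'   `specific_activity` (mg min^-1 mg^-1), `sd`, `clipped`.
#' @export
absorbance_to_specific_activity <- function(delta_a660, calibration_slope,
                                            reaction_minutes, enzyme_mg,
                                            condition = "no acceptor",
                                            acceptor_concentration = NA_real_,
                                            sd = NA_real_) {
  assert_scalar_num(calibration_slope, "calibration_slope", positive = TRUE)
  assert_scalar_num(reaction_minutes, "reaction_minutes", positive = TRUE)
  assert_scalar_num(enzyme_mg, "enzyme_mg", positive = TRUE)
  assert_scalar_num(delta_a660, "delta_a660")
  clipped <- delta_a660 < 0
  if (clipped) {
    warning("Negative delta A660 clipped to 0.", call. = FALSE)
    delta_a660 <- 0
  }
  ug_per_min_per_mg <- delta_a660 * calibration_slope / reaction_minutes / enzyme_mg
  tibble::tibble(condition = condition,
                 acceptor_concentration = acceptor_concentration,
                 specific_activity = ug_per_min_per_mg / 1000,  # ug -> mg
                 sd = sd, clipped = clipped)
}

#' Transglycosylation factor
#'
#' Ratio of the amylose degradation activity in the presence of an acceptor
#' sugar to the activity without acceptor. When standard deviations are
#' supplied the SD of the ratio is propagated to first order.
#'
#' @param with_acceptor Specific activity with acceptor (> 0 scale), or a
#'   one-row activity tibble as returned by
#'   [absorbance_to_specific_activity()].
#' @param without_acceptor Baseline specific activity (> 0), or an activity
#'   tibble row.
#' @param with_sd,without_sd Optional SDs (ignored when tibbles carry `sd`).
#' @return One-row tibble: `factor`, `sd`.
#' @export
transglycosylation_factor <- function(with_acceptor, without_acceptor,
                                      with_sd = NA_real_, without_sd = NA_real_) {
  if (is.data.frame(with_acceptor)) {
    with_sd <- with_acceptor$sd[1]
    with_acceptor <- with_acceptor$specific_activity[1]
  }
  if (is.data.frame(without_acceptor)) {
    without_sd <- without_acceptor$sd[1]
    without_acceptor <- without_acceptor$specific_activity[1]
  }
  assert_scalar_num(with_acceptor, "with_acceptor", nonneg = TRUE)
  if (!is.numeric(without_acceptor) || length(without_acceptor) != 1L ||
      !is.finite(without_acceptor) || without_acceptor <= 0) {
    stop_gt("Baseline (no-acceptor) activity must be > 0.", "gt_division_error")
  }
  f <- with_acceptor / without_acceptor
  f_sd <- if (is.finite(with_sd) && is.finite(without_sd) && with_acceptor > 0) {
    f * sqrt((with_sd / with_acceptor)^2 + (without_sd / without_acceptor)^2)
  } else {
    NA_real_
  }
  tibble::tibble(factor = f, sd = f_sd)
}

#' Transglycosylation factors for a whole activity table
#'
#' @param activity Tibble of activity rows (see
#'   [absorbance_to_specific_activity()]), one of which is the baseline.
#' @param baseline `condition` value of the no-acceptor row.
#' @return Tibble with one row per non-baseline condition: `condition`,
#'   `specific_activity`, `sd`, `factor`, `factor_sd`.
#' @export
transglycosylation_factors <- function(activity, baseline = "no acceptor") {
  base <- activity[activity$condition == baseline, ]
  if (nrow(base) != 1) {
    stop_gt(sprintf("Expected exactly one baseline row with condition '%s'.", baseline),
            "gt_validation_error")
  }
  activity |>
    dplyr::filter(.data$condition != baseline) |>
    dplyr::rowwise() |>
    dplyr::mutate(tf = list(transglycosylation_factor(
      .data$specific_activity, base$specific_activity,
      .data$sd, base$sd))) |>
    dplyr::ungroup() |>
    tidyr::unnest_wider("tf", names_sep = "_") |>
    dplyr::rename(factor = "tf_factor", factor_sd = "tf_sd") |>
    dplyr::select("condition", "specific_activity", "sd", "factor", "factor_sd")
}

#' Molar enzyme concentration from mass concentration
#'
#' @param enzyme_concentration Enzyme, mg/ml (equivalently g/l).
#' @param enzyme_molar_mass Molar mass, Da (g/mol).
#' @return Enzyme concentration in uM.
#' @export
enzyme_molar_concentration <- function(enzyme_concentration, enzyme_molar_mass) {
  assert_scalar_num(enzyme_concentration, "enzyme_concentration", positive = TRUE)
  assert_scalar_num(enzyme_molar_mass, "enzyme_molar_mass", positive = TRUE)
  enzyme_concentration / enzyme_molar_mass * 1e6
}

#' Convert a fitted Vmax to a turnover number
#'
#' @param vmax Maximal velocity, uM product min^-1.
#' @param enzyme_concentration Enzyme, mg/ml.
#' @param enzyme_molar_mass Molar mass, Da.
#' @return kcat in min^-1.
#' @export
vmax_to_kcat <- function(vmax, enzyme_concentration, enzyme_molar_mass) {
  assert_scalar_num(vmax, "vmax", nonneg = TRUE)
  vmax / enzyme_molar_concentration(enzyme_concentration, enzyme_molar_mass)
}

#' Fit Michaelis-Menten parameters by the Lineweaver-Burk method
#'
#' Ordinary least squares on the double-reciprocal transform: 1/v against
#' 1/[S]. The intercept is 1/Vmax and the slope KM/Vmax. When the enzyme
#' concentration and molar mass are supplied, Vmax is also converted to a
#' turnover number and the catalytic efficiency kcat/KM is reported.
#'
#' @param data Data frame of initial-velocity points.
#' @param conc_col,velocity_col Column names (defaults `concentration_mM`,
#'   `velocity`; velocities in uM min^-1 if kcat is wanted in min^-1).
#' @param enzyme_concentration Optional enzyme load, mg/ml.
#' @param enzyme_molar_mass Optional molar mass, Da.
#' @return An object of class `lb_fit` with elements `KM` (mM), `Vmax`,
#'   `kcat` (min^-1 or NA), `efficiency` (kcat/KM or NA), `r_squared`,
#'   `n`, the underlying `lm` fit and the data. Supports [tidy()],
#'   [glance()] and `autoplot()`.
#' @export
fit_lineweaver_burk <- function(data, conc_col = "concentration_mM",
                                velocity_col = "velocity",
                                enzyme_concentration = NULL,
                                enzyme_molar_mass = NULL) {
  s <- data[[conc_col]]
  v <- data[[velocity_col]]
  if (is.null(s) || is.null(v)) {
    stop_gt(sprintf("Columns '%s' and '%s' are required.", conc_col, velocity_col),
            "gt_validation_error")
  }
  keep <- is.finite(s) & is.finite(v)
  s <- s[keep]; v <- v[keep]
  if (length(unique(s)) < 3) {
    stop_gt("Need at least 3 points with distinct concentrations.", "gt_validation_error")
  }
  if (any(s <= 0)) stop_gt("Concentrations must be > 0.", "gt_validation_error")
  if (any(v <= 0)) stop_gt("Velocities must be > 0 for the reciprocal transform.",
                           "gt_validation_error")
  df <- tibble::tibble(inv_s = 1 / s, inv_v = 1 / v)
  fit <- stats::lm(inv_v ~ inv_s, data = df)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(intercept) || intercept <= 0) {
    stop_gt("Non-positive Lineweaver-Burk intercept: data are inconsistent with Michaelis-Menten saturation.",
            "gt_fit_failure_error")
  }
  vmax <- 1 / intercept
  km <- slope / intercept
  if (km < 0) {
    stop_gt("Negative fitted KM: data are inconsistent with Michaelis-Menten kinetics.",
            "gt_fit_failure_error")
  }
  tss <- sum((df$inv_v - mean(df$inv_v))^2)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (tss < .Machine$double.eps^0.5) 1 else 1 - rss / tss

  kcat <- efficiency <- NA_real_
  if (!is.null(enzyme_concentration) && !is.null(enzyme_molar_mass)) {
    kcat <- vmax_to_kcat(vmax, enzyme_concentration, enzyme_molar_mass)
    efficiency <- kcat / km
  }
  structure(list(KM = km, Vmax = vmax, kcat = kcat, efficiency = efficiency,
                 r_squared = r2, n = length(s), lm_fit = fit,
                 enzyme_concentration = enzyme_concentration,
                 enzyme_molar_mass = enzyme_molar_mass,
                 data = tibble::tibble(concentration_mM = s, velocity = v)),
            class = "lb_fit")
}

#' Direct nonlinear Michaelis-Menten fit (cross-check route)
#'
#' Fits v = Vmax [S] / (KM + [S]) by nonlinear least squares, started from
#' the Lineweaver-Burk estimates. This is the statistically preferable fit
#' and serves as an independent cross-check of the double-reciprocal method,
#' which remains the reported route.
#'
#' @inheritParams fit_lineweaver_burk
#' @return An `lb_fit`-shaped object of class `c("mm_fit", "lb_fit")`.
#' @export
fit_michaelis_menten <- function(data, conc_col = "concentration_mM",
                                 velocity_col = "velocity",
                                 enzyme_concentration = NULL,
                                 enzyme_molar_mass = NULL) {
  lb <- fit_lineweaver_burk(data, conc_col, velocity_col,
                            enzyme_concentration, enzyme_molar_mass)
  df <- lb$data
  start_km <- if (lb$KM > 0) lb$KM else stats::median(df$concentration_mM)
  fit <- stats::nls(velocity ~ vmax * concentration_mM / (km + concentration_mM),
                    data = df, start = list(vmax = lb$Vmax, km = start_km))
  co <- stats::coef(fit)
  vmax <- unname(co[["vmax"]]); km <- unname(co[["km"]])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((df$velocity - mean(df$velocity))^2)
  kcat <- efficiency <- NA_real_
  if (!is.null(enzyme_concentration) && !is.null(enzyme_molar_mass)) {
    kcat <- vmax_to_kcat(vmax, enzyme_concentration, enzyme_molar_mass)
    efficiency <- kcat / km
  }
  structure(list(KM = km, Vmax = vmax, kcat = kcat, efficiency = efficiency,
                 r_squared = if (tss < .Machine$double.eps^0.5) 1 else 1 - rss / tss,
                 n = nrow(df), lm_fit = fit,
                 enzyme_concentration = enzyme_concentration,
                 enzyme_molar_mass = enzyme_molar_mass, data = df),
            class = c("mm_fit", "lb_fit"))
}

#' Catalytic efficiency kcat/KM
#'
#' @param fit An `lb_fit` (with kcat available), or a numeric kcat when `km`
#'   is given.
#' @param km Michaelis constant, mM (only when `fit` is numeric).
#' @return Efficiency in min^-1 mM^-1.
#' @export
efficiency_ratio <- function(fit, km = NULL) {
  if (inherits(fit, "lb_fit")) {
    if (!is.finite(fit$kcat)) {
      stop_gt("Fit carries no kcat; supply enzyme concentration and molar mass.",
              "gt_validation_error")
    }
    kcat <- fit$kcat
    km <- fit$KM
  } else {
    kcat <- fit
  }
  assert_scalar_num(kcat, "kcat", nonneg = TRUE)
  assert_scalar_num(km, "km", positive = TRUE)
  kcat / km
}

#' @export
print.lb_fit <- function(x, ...) {
  cat(sprintf("%s fit: KM = %.4g mM, Vmax = %.6g (n = %d, R^2 = %.4f)\n",
              if (inherits(x, "mm_fit")) "Michaelis-Menten" else "Lineweaver-Burk",
              x$KM, x$Vmax, x$n, x$r_squared))
  if (is.finite(x$kcat)) {
    cat(sprintf("  kcat = %.6g min^-1, kcat/KM = %.6g min^-1 mM^-1\n",
                x$kcat, x$efficiency))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.lb_fit <- function(x, ...) {
  tibble::tibble(
    term = c("KM", "Vmax", "kcat", "efficiency"),
    estimate = c(x$KM, x$Vmax, x$kcat, x$efficiency),
    unit = c("mM", "velocity units", "min^-1", "min^-1 mM^-1")
  )
}

#' @export
glance.lb_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n,
                 enzyme_concentration = x$enzyme_concentration %||% NA_real_,
                 enzyme_molar_mass = x$enzyme_molar_mass %||% NA_real_)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.lb_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data,
                      inv_s = 1 / .data$concentration_mM,
                      inv_v = 1 / .data$velocity)
  ggplot2::ggplot(df, ggplot2::aes(.data$inv_s, .data$inv_v)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 1 / object$Vmax,
                         slope = object$KM / object$Vmax,
                         linetype = 2) +
    ggplot2::labs(x = expression(1 / "[S] (1/mM)"),
                  y = expression(1 / v),
                  title = sprintf("Lineweaver-Burk: KM = %.3g mM", object$KM)) +
    ggplot2::theme_minimal()
}
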