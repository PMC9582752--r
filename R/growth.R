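#' Specific growth rate from the exponential portion of a growth curve
#'
#' The specific growth rate k (h^-1) is the slope of an ordinary
#' least-squares regression of ln(cell density) on time inside the
#' exponential-phase window. When no window is supplied, the longest
#' contiguous window of at least 4 points with a log-linear R^2 of at least
#' 0.99 is selected automatically (ties going to the earlier window); if no
#' window reaches 0.99 the best-R^2 window of at least 4 points is used.
#'
#' @param data Data frame of the growth curve.
#' @param window Optional numeric `c(t_start, t_end)` in hours delimiting
#'   the exponential phase.
#' @param time_col,density_col Column names (defaults `time_h`, `density`).
#' @param min_points Minimum window size for automatic selection (default 4).
#' @param r2_threshold Automatic-selection R^2 cutoff (default 0.99).
#' @return An object of class `growth_fit`: `k` (h^-1), `r_squared`,
#'   `window`, `n`, the `lm` fit and data. Supports [tidy()], [glance()]
#'   and `autoplot()`.
#' @export
fit_growth_rate <- function(data, window = NULL, time_col = "time_h",
                            density_col = "density", min_points = 4L,
                            r2_threshold = 0.99) {
  t <- data[[time_col]]
  n <- data[[density_col]]
  if (is.null(t) || is.null(n)) {
    stop_gt(sprintf("Columns '%s' and '%s' are required.", time_col, density_col),
            "gt_validation_error")
  }
  ord <- order(t)
  t <- t[ord]; n <- n[ord]
  if (any(diff(t) <= 0)) stop_gt("Times must be strictly increasing.", "gt_validation_error")

  if (is.null(window)) {
    window <- auto_exponential_window(t, n, min_points, r2_threshold)
  }
  inside <- t >= window[1] & t <= window[2]
  tw <- t[inside]; nw <- n[inside]
  if (length(tw) < 3) stop_gt("Need at least 3 points inside the window.", "gt_validation_error")
  if (any(nw <= 0)) stop_gt("Densities inside the window must be > 0.", "gt_validation_error")

  fit <- stats::lm(log(nw) ~ tw)
  k <- unname(stats::coef(fit)[2])
  structure(list(k = k, r_squared = loglinear_r2(tw, nw),
                 window = c(t_start = window[1], t_end = window[2]),
                 n = length(tw), lm_fit = fit,
                 data = tibble::tibble(time_h = t, density = n)),
            class = "growth_fit")
}

loglinear_r2 <- function(t, n) {
  y <- log(n)
  fit <- stats::lm(y ~ t)
  tss <- sum((y - mean(y))^2)
  rss <- sum(stats::residuals(fit)^2)
  if (tss < .Machine$double.eps^0.5) {
    # flat on the log scale: a zero-slope line fits exactly
    return(1)
  }
  1 - rss / tss
}

auto_exponential_window <- function(t, n, min_points, r2_threshold) {
  np <- length(t)
  if (np < min_points) {
    stop_gt(sprintf("Need at least %d points for automatic window selection.", min_points),
            "gt_validation_error")
  }
  # flat-in-log windows (lag or stationary plateaus) are not exponential
  # growth: they never qualify, even though a zero-slope line fits exactly
  best <- NULL
  all_flat <- TRUE
  for (i in seq_len(np - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, np)) {
      if (any(n[i:j] <= 0)) next
      y <- log(n[i:j])
      flat <- stats::var(y) < .Machine$double.eps^0.5
      if (!flat) all_flat <- FALSE
      r2 <- if (flat) -Inf else loglinear_r2(t[i:j], n[i:j])
      cand <- list(i = i, j = j, len = j - i + 1L, r2 = r2)
      if (is.null(best)) { best <- cand; next }
      if (r2 >= r2_threshold && best$r2 >= r2_threshold) {
        # both qualify: longer wins, ties -> earlier
        if (cand$len > best$len) best <- cand
      } else if (r2 >= r2_threshold && best$r2 < r2_threshold) {
        best <- cand
      } else if (best$r2 < r2_threshold && r2 > best$r2) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop_gt("No usable window with positive densities.", "gt_validation_error")
  }
  if (all_flat) return(c(t[1], t[np]))  # constant curve: k = 0 over everything
  c(t[best$i], t[best$j])
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Specific growth rate k = %.4g h^-1 (window %.3g-%.3g h, n = %d, R^2 = %.4f)\n",
              x$k, x$window[1], x$window[2], x$n, x$r_squared))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = "k", estimate = x$k, unit = "h^-1")
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n,
                 t_start = x$window[["t_start"]], t_end = x$window[["t_end"]])
}

#' @export
autoplot.growth_fit <- function(object, ...) {
  df <- object$data
  inwin <- df$time_h >= object$window[1] & df$time_h <= object$window[2]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$density)) +
    ggplot2::geom_point(ggplot2::aes(colour = inwin)) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey60"),
                                 name = "exponential window") +
    ggplot2::labs(x = "time (h)", y = "cell density (cells/ml)",
                  title = sprintf("k = %.3g / h", object$k)) +
    ggplot2::theme_minimal()
}
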