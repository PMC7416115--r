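#' GDP-production kinetics series
#'
#' A %GDP versus time series from a nucleotide-hydrolysis assay, as
#' produced by HPLC quantification of GDP/GTP content.
#'
#' @param times minutes, strictly increasing from 0.
#' @param gdp_percent %GDP values in `[0, 100]`.
#' @param condition label (GAP, substrate).
#' @return Object of class `"kinetics_series"`.
#' @export
kinetics_series <- function(times, gdp_percent, condition = "condition") {
  check_that(length(times) >= 4 && length(gdp_percent) == length(times),
             "a kinetics series needs >= 4 matching time points")
  check_that(all(is.finite(times)) && times[1] >= 0 && all(diff(times) > 0),
             "times must be non-negative and strictly increasing")
  check_that(all(is.finite(gdp_percent)) &&
               all(gdp_percent >= 0 & gdp_percent <= 100),
             "%GDP values must lie in [0, 100]")
  structure(list(times = as.numeric(times),
                 gdp_percent = as.numeric(gdp_percent),
                 condition = condition),
            class = "kinetics_series")
}

# OLS slope/intercept/r2 via closed form; r2 defined as 0 for a flat
# (zero-variance) response.
ols_fit <- function(t, y) {
  n <- length(t)
  mt <- mean(t); my <- mean(y)
  sxx <- sum((t - mt)^2)
  if (sxx == 0) abort_param("zero time variance in fit window")
  syy <- sum((y - my)^2)
  sxy <- sum((t - mt) * (y - my))
  slope <- sxy / sxx
  r2 <- if (syy == 0) 0 else (sxy^2) / (sxx * syy)
  list(slope = slope, intercept = my - slope * mt, r2 = r2)
}

#' Initial linear rate of GDP production
#'
#' Fits ordinary least squares lines over windows starting at the first
#' time point, with lengths from `min_len` up to `min(max_len, n)`
#' points, and returns the longest window whose r-squared reaches
#' `r2_accept`; if none qualifies, the window with maximal r-squared is
#' used. The slope of the chosen window is the rate. For a flat series
#' the rate is 0 and r-squared is reported as 0 by convention (the fit
#' is flagged).
#'
#' @param series a [kinetics_series()].
#' @param min_len,max_len window length bounds, points (defaults 4 and 8).
#' @param r2_accept r-squared acceptance level for extending the window.
#' @return Object of class `"rate_fit"`: `rate` (%/min), `intercept`,
#'   `window` (`start_index`, `length`), `r_squared`, `flat` flag.
#' @export
linear_rate <- function(series, min_len = 4L, max_len = 8L,
                        r2_accept = 0.98) {
  stopifnot(inherits(series, "kinetics_series"))
  n <- length(series$times)
  check_that(n >= min_len, "series shorter than the minimum fit window")
  check_that(min_len >= 2 && max_len >= min_len,
             "need max_len >= min_len >= 2")
  lens <- seq(min_len, min(max_len, n))
  fits <- lapply(lens, function(L) {
    ols_fit(series$times[1:L], series$gdp_percent[1:L])
  })
  r2s <- vapply(fits, `[[`, 0, "r2")
  ok <- which(r2s >= r2_accept)
  pick <- if (length(ok)) ok[length(ok)] else which.max(r2s)
  f <- fits[[pick]]
  structure(list(rate = f$slope, intercept = f$intercept,
                 window = c(start_index = 1L, length = lens[pick]),
                 r_squared = f$r2,
                 flat = stats::var(series$gdp_percent[1:lens[pick]]) == 0,
                 condition = series$condition),
            class = "rate_fit")
}

#' Relative GAP activity between two rate fits
#'
#' Compares GAP-stimulated rates after subtracting the intrinsic
#' (GAP-free) hydrolysis rate: `activity = rate - intrinsic_rate`
#' (floored at 0). Reports the fold activity of `control` relative to
#' `test` and the percent reduction, so a control with a quarter of the
#' test's activity is reported as a 75% reduction. Set
#' `subtract_intrinsic = FALSE` to compare raw rates.
#'
#' @param test,control [linear_rate()] fits to compare.
#' @param intrinsic [linear_rate()] fit of the intrinsic (no-GAP)
#'   reaction, or `NULL` for zero.
#' @param subtract_intrinsic subtract the intrinsic rate first?
#' @return List with `fold` (control activity / test activity) and
#'   `percent_reduction` (`100 * (1 - fold)`); both `NA` (flagged via
#'   warning) when the test activity is zero.
#' @export
relative_activity <- function(test, control, intrinsic = NULL,
                              subtract_intrinsic = TRUE) {
  stopifnot(inherits(test, "rate_fit"), inherits(control, "rate_fit"))
  base <- if (!is.null(intrinsic) && subtract_intrinsic) {
    stopifnot(inherits(intrinsic, "rate_fit"))
    intrinsic$rate
  } else 0
  check_that(test$rate >= 0 && control$rate >= 0,
             "rates must be non-negative")
  act_test <- max(test$rate - base, 0)
  act_control <- max(control$rate - base, 0)
  if (act_test == 0) {
    warning("test activity is zero after intrinsic subtraction; ",
            "relative activity undefined")
    return(list(fold = NA_real_, percent_reduction = NA_real_))
  }
  fold <- act_control / act_test
  list(fold = fold, percent_reduction = 100 * (1 - fold))
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "<rate_fit> %s: %.3f %%GDP/min over first %d points (r2 = %.4f)%s\n",
    x$condition, x$rate, x$window[["length"]], x$r_squared,
    if (isTRUE(x$flat)) " [flat series]" else ""))
  invisible(x)
}
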