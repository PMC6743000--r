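# Seasonal cosine model for intra-tooth d18O: places each enamel band on a
# 365-day calendar ("Julian days", day 0 = January 15th), normalising
# inter-individual differences in eruption timing and growth rate.

# Linear subproblem: at fixed period X, d18O(x) = M + B cos(2 pi x / X) +
# C sin(2 pi x / X) is linear in (M, B, C); amplitude/phase follow from
# (B, C). Only X needs a 1-D search.
cosine_rss <- function(x, y, X) {
  w <- 2 * pi * x / X
  fit <- stats::lm.fit(cbind(1, cos(w), sin(w)), y)
  sum(fit$residuals^2)
}

cosine_coef <- function(x, y, X) {
  w <- 2 * pi * x / X
  fit <- stats::lm.fit(cbind(1, cos(w), sin(w)), y)
  cf <- fit$coefficients
  A <- sqrt(cf[2]^2 + cf[3]^2)
  # cos(w - phi) expansion: B = A cos(phi), C = A sin(phi); x0 = phi X / 2pi
  x0 <- (atan2(cf[3], cf[2]) / (2 * pi) * X) %% X
  list(M = unname(cf[1]), A = unname(A), x0 = unname(x0),
       rmse = sqrt(mean(fit$residuals^2)), fitted = fit$fitted.values)
}

#' Fit a seasonal cosine to an intra-tooth d18O sequence
#'
#' Least-squares fit of `d18O(x) = M + A cos(2 pi (x - x0) / X)` over band
#' positions `x` (mm from cervix). At fixed period `X` the model is linear
#' in mean, amplitude and phase components; `X` is profiled over
#' `period_bounds` on a grid and refined by golden-section search. The
#' phase convention keeps `A >= 0` and `x0` in `[0, X)`.
#'
#' @param series data frame with columns `position_mm` and `d18O_apa`
#'   (additional columns are ignored); at least 6 bands and a positional
#'   span of at least half the lower period bound are required.
#' @param period_bounds allowed period range in mm (default 15-45 mm,
#'   covering annual molar growth of caprines and cattle).
#' @param grid_step grid resolution for the period search in mm.
#' @return An object of class `seasonal_fit` with elements `M` (mean,
#'   permil), `A` (amplitude, permil, >= 0), `X` (period, mm), `x0`
#'   (position of the d18O maximum, mm), `rmse`, `n`, and `day_per_band`
#'   (`NA` until [assign_julian_days()] is called).
#' @export
fit_seasonal_cosine <- function(series, period_bounds = c(15, 45),
                                grid_step = 0.5) {
  stopifnot(is.data.frame(series),
            all(c("position_mm", "d18O_apa") %in% names(series)),
            length(period_bounds) == 2, period_bounds[1] > 0,
            period_bounds[2] > period_bounds[1], grid_step > 0)
  x <- series$position_mm
  y <- series$d18O_apa
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite position or d18O value")
  }
  if (length(x) < 6) stop("at least 6 bands required for a seasonal fit")
  if (diff(range(x)) < period_bounds[1] / 2) {
    stop("insufficient seasonal coverage: positions span ",
         signif(diff(range(x)), 3), " mm, need >= ", period_bounds[1] / 2)
  }

  grid <- seq(period_bounds[1], period_bounds[2], by = grid_step)
  rss <- vapply(grid, function(X) cosine_rss(x, y, X), numeric(1))
  best <- which.min(rss)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(function(X) cosine_rss(x, y, X),
                         lower = lo, upper = hi, tol = 1e-9)
  X <- opt$minimum
  cf <- cosine_coef(x, y, X)
  structure(list(M = cf$M, A = cf$A, X = X, x0 = cf$x0, rmse = cf$rmse,
                 n = length(x), fitted = unname(cf$fitted),
                 day_per_band = rep(NA_real_, length(x))),
            class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf(
    "Seasonal cosine fit: M = %.2f, A = %.2f permil, X = %.2f mm, x0 = %.2f mm (rmse %.3f, n = %d)\n",
    x$M, x$A, x$X, x$x0, x$rmse, x$n))
  if (!all(is.na(x$day_per_band))) {
    cat(sprintf("  day-of-year assigned to %d bands (0 = Jan 15)\n",
                sum(!is.na(x$day_per_band))))
  }
  invisible(x)
}

#' Assign a day of year to each enamel band
#'
#' Maps each band's cosine phase to a day of year with the d18O maximum
#' anchored to `peak_day` (default 182, mid-July) and day 0 = January 15th.
#' Positions are measured from the cervix; enamel closer to the cervix was
#' deposited later, so by default time advances as position decreases
#' (`time_toward_cervix`). The mapping is invariant under `x0 -> x0 + k X`.
#'
#' @param series data frame with column `position_mm`.
#' @param fit a `seasonal_fit` from [fit_seasonal_cosine()].
#' @param peak_day day of year (0 = Jan 15) anchored to the d18O maximum.
#' @param time_toward_cervix if `TRUE` (default), deposition time increases
#'   toward the cervix (decreasing position); set `FALSE` to flip.
#' @return The `seasonal_fit` with `day_per_band` populated (values in
#'   `[0, 365)`).
#' @export
assign_julian_days <- function(series, fit, peak_day = 182,
                               time_toward_cervix = TRUE) {
  stopifnot(inherits(fit, "seasonal_fit"), is.data.frame(series),
            "position_mm" %in% names(series))
  if (!is.finite(fit$X) || fit$X <= 0) stop("invalid period X")
  phase <- (series$position_mm - fit$x0) / fit$X
  sign <- if (time_toward_cervix) -1 else 1
  fit$day_per_band <- (peak_day + sign * 365 * phase) %% 365
  fit
}

# Calendar two-month bins over a 365-day year (Jan-Feb, ..., Nov-Dec).
bimonth_levels <- function() {
  c("Jan-Feb", "Mar-Apr", "May-Jun", "Jul-Aug", "Sep-Oct", "Nov-Dec")
}

# day: day of year with 0 = Jan 15; returns the calendar two-month bin.
bimonth_of_day <- function(day) {
  stopifnot(all(day >= 0 & day < 365))
  calendar <- (day + 14) %% 365  # 0 = Jan 1
  month_end <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  month <- findInterval(calendar, c(0, month_end[-12]))
  factor(bimonth_levels()[ceiling(month / 2)], levels = bimonth_levels())
}

#' Bin a tooth's d13C sequence by two-month intervals
#'
#' Converts each band's assigned day of year to its calendar two-month
#' interval and averages d13C_apa within each interval. All six bins are
#' always emitted; bins with no assigned bands carry `NA` means (never
#' zero-filled).
#'
#' @param series data frame with column `d13C_apa` (identifier columns
#'   `tooth_id`, `site`, `period`, `taxon` are propagated when present).
#' @param day_of_year either a numeric vector of days (0 = Jan 15) or a
#'   `seasonal_fit` with `day_per_band` populated.
#' @return Data frame with one row per bin: identifier columns, `bimonth`,
#'   `n_bands`, `mean_d13C_apa`.
#' @export
bin_bimonthly <- function(series, day_of_year) {
  stopifnot(is.data.frame(series), "d13C_apa" %in% names(series))
  if (inherits(day_of_year, "seasonal_fit")) {
    day_of_year <- day_of_year$day_per_band
  }
  stopifnot(length(day_of_year) == nrow(series))
  if (anyNA(day_of_year)) stop("day assignments missing; run assign_julian_days first")
  bin <- bimonth_of_day(day_of_year)
  n_bands <- as.integer(table(bin))
  means <- tapply(series$d13C_apa, bin, mean)
  out <- data.frame(bimonth = bimonth_levels(),
                    n_bands = n_bands,
                    mean_d13C_apa = as.numeric(means[bimonth_levels()]))
  for (col in c("taxon", "period", "site", "tooth_id")) {
    if (col %in% names(series)) out <- cbind(stats::setNames(
      data.frame(series[[col]][1]), col), out)
  }
  out
}
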