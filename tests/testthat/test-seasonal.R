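make_cosine_series <- function(M = -8, A = 2, X = 30, x0 = 10,
                               positions = 0:29, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- M + A * cos(2 * pi * (positions - x0) / X)
  if (noise_sd > 0) y <- y + rnorm(length(positions), 0, noise_sd)
  data.frame(position_mm = positions, d18O_apa = y)
}

test_that("noiseless cosine parameters are recovered essentially exactly", {
  series <- make_cosine_series()
  fit <- fit_seasonal_cosine(series)
  expect_equal(fit$M, -8, tolerance = 1e-6)
  expect_equal(fit$A, 2, tolerance = 1e-6)
  expect_equal(fit$X, 30, tolerance = 1e-6)
  expect_equal(fit$x0 %% 30, 10, tolerance = 1e-5)
  expect_lt(fit$rmse, 1e-7)
  expect_true(fit$A >= 0)
})

test_that("noisy fit matches the dense (X, x0) grid-search oracle", {
  series <- make_cosine_series(noise_sd = 0.07, seed = 31)
  fit <- fit_seasonal_cosine(series)
  oracle <- cosine_grid_oracle(series$position_mm, series$d18O_apa)
  # the oracle grid is 0.1 mm in X and ~0.17 mm in phase; agree within that
  expect_equal(fit$X, oracle$X, tolerance = 0.15)
  expect_equal(fit$x0 %% fit$X, oracle$x0 %% oracle$X, tolerance = 0.3)
  expect_lte(sum((series$d18O_apa - fit$fitted)^2), oracle$rss + 1e-9)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_seasonal_cosine(make_cosine_series(positions = 0:4)),
               "6 bands")
  expect_error(fit_seasonal_cosine(make_cosine_series(positions = 0:6)),
               "insufficient seasonal coverage")
  bad <- make_cosine_series()
  bad$d18O_apa[3] <- NA
  expect_error(fit_seasonal_cosine(bad), "non-finite")
})

test_that("day assignment anchors the d18O peak and respects periodicity", {
  series <- make_cosine_series()
  fit <- fit_seasonal_cosine(series)

  # band at x = x0 maps to the configured peak day
  probe <- data.frame(position_mm = c(fit$x0, fit$x0 + fit$X, fit$x0 + 7),
                      d18O_apa = 0)
  days <- assign_julian_days(probe, fit)$day_per_band
  expect_equal(days[1], 182, tolerance = 1e-6)
  # two bands exactly X mm apart share a day
  expect_equal(days[1], days[2], tolerance = 1e-6)
  # phase identity: x0 -> x0 + kX leaves assignments unchanged
  fit_shift <- fit
  fit_shift$x0 <- fit$x0 + 3 * fit$X
  days_shift <- assign_julian_days(probe, fit_shift)$day_per_band
  expect_equal(days, days_shift, tolerance = 1e-8)
  # custom peak day honoured
  expect_equal(assign_julian_days(probe, fit, peak_day = 200)$day_per_band[1],
               200, tolerance = 1e-6)
  expect_true(all(days >= 0 & days < 365))
  bad <- fit
  bad$X <- -1
  expect_error(assign_julian_days(probe, bad), "invalid period")
})

test_that("assigned days invert the noiseless forward model", {
  sim <- simulate_tooth_series(schedule = fodder_schedule(pulse = 0.5),
                               noise = noise_model(0, 0, 0, 0))
  fit <- fit_seasonal_cosine(sim$series)
  fit <- assign_julian_days(sim$series, fit)
  err <- day_abs_error(fit$day_per_band, sim$truth$day_true)
  expect_lt(mean(err), 0.1)

  # with analytical noise the error stays within the oracle-informed bound:
  # sd(day) ~ (365 / (2 pi A_eff)) * sd_noise per band, well under 10 days
  sim_n <- simulate_tooth_series(schedule = fodder_schedule(pulse = 0.5),
                                 seed = 8)
  fit_n <- assign_julian_days(sim_n$series,
                              fit_seasonal_cosine(sim_n$series))
  expect_lt(mean(day_abs_error(fit_n$day_per_band, sim_n$truth$day_true)), 10)
})

test_that("amplitude recovery within 10% across 20 noisy replicates", {
  ok <- vapply(1:20, function(i) {
    series <- make_cosine_series(A = 2, X = 24, positions = 0:29,
                                 noise_sd = 0.07, seed = 400 + i)
    fit <- fit_seasonal_cosine(series)
    abs(fit$A - 2) / 2 < 0.1
  }, logical(1))
  expect_true(all(ok))
})

test_that("bimonthly binning is an exact partition matching the brute-force means", {
  # all bands in mid-January at -6: Jan-Feb bin only
  series <- data.frame(d13C_apa = rep(-6, 5), tooth_id = "T1")
  b <- bin_bimonthly(series, rep(c(0, 5, 10, 12, 14), 1))
  expect_equal(nrow(b), 6)
  expect_equal(b$mean_d13C_apa[b$bimonth == "Jan-Feb"], -6)
  expect_true(all(is.na(b$mean_d13C_apa[b$bimonth != "Jan-Feb"])))
  expect_equal(sum(b$n_bands), 5)

  # uniform day coverage: per-bin means equal direct partition means
  set.seed(61)
  days <- runif(200, 0, 365)
  vals <- rnorm(200, -9, 2)
  series2 <- data.frame(d13C_apa = vals)
  b2 <- bin_bimonthly(series2, days)
  calendar <- (days + 14) %% 365
  edges <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  bin_idx <- ceiling(findInterval(calendar, c(0, edges[-12])) / 2)
  brute <- tapply(vals, bin_idx, mean)
  expect_equal(b2$mean_d13C_apa, as.numeric(brute[as.character(1:6)]))
  expect_equal(sum(b2$n_bands), 200)
  expect_error(bin_bimonthly(series2, c(days[-1], NA)), "missing")
})
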