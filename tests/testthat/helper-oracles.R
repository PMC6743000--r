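# Independent oracles and shared fixtures for the test suite. Each oracle
# is a direct/brute-force computation kept deliberately separate from the
# package's implementation paths.

# Exact Mann-Whitney U by exhaustive pair enumeration (half credit for
# ties); usable whenever n_a * n_b is small.
mwu_exact_oracle <- function(a, b) {
  gt <- sum(outer(a, b, ">"))
  ties <- sum(outer(a, b, "=="))
  gt + ties / 2
}

# Pearson r from the raw covariance formula.
pearson_r_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Uniform moving average of a periodic daily function over a centred
# window, computed by explicit convolution at the same ~1-day resolution
# used by the simulator's contract.
convolve_schedule_oracle <- function(f, t, window) {
  m <- max(1L, as.integer(round(window)))
  offsets <- (seq_len(m) - (m + 1) / 2) * (window / m)
  vapply(t, function(tt) mean(f(tt + offsets)), numeric(1))
}

# Dense grid search over (X, x0) with the mean/amplitude subproblem solved
# by ordinary least squares at each node; the reference answer for the
# noisy cosine fit.
cosine_grid_oracle <- function(x, y, X_range = c(15, 45), nX = 301,
                               nphi = 181) {
  best <- list(rss = Inf)
  for (X in seq(X_range[1], X_range[2], length.out = nX)) {
    for (x0 in seq(0, X, length.out = nphi)) {
      basis <- cos(2 * pi * (x - x0) / X)
      fit <- stats::lm.fit(cbind(1, basis), y)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) {
        best <- list(rss = rss, X = X, x0 = x0,
                     M = unname(fit$coefficients[1]),
                     A = unname(fit$coefficients[2]))
      }
    }
  }
  if (best$A < 0) {
    best$A <- -best$A
    best$x0 <- (best$x0 + best$X / 2) %% best$X
  }
  best
}

# Hamming distance by direct position-wise comparison (no N handling).
hamming_oracle <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Circular absolute difference between days of year.
day_abs_error <- function(est, truth) {
  abs(((est - truth + 182.5) %% 365) - 182.5)
}

# A small fixed haplotype panel with hand-placed diagnostic sites, used
# where tests need full control over distances.
toy_panel <- function() {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = 40), collapse = "")
  s1 <- base
  s2 <- base; substr(s2, 5, 5) <- "T"; substr(s2, 11, 11) <- "A"
  s3 <- base; substr(s3, 20, 20) <- "A"; substr(s3, 21, 21) <- "C"
  substr(s3, 30, 30) <- "G"
  panel <- data.frame(
    id = c("h1", "h2", "h3"),
    taxon = c("Ovis aries", "Ovis ammon", "Capra sibirica"),
    status = c("domestic", "wild", "wild"),
    sequence = c(s1, s2, s3))
  class(panel) <- c("haplotype_panel", "data.frame")
  panel
}

# Six-tooth winter-foddering herd used by the end-to-end checks: shared
# calendar-locked schedule, individual birth days and growth rates.
simulate_herd <- function(seed, pulse = 0.5, n_teeth = 6) {
  set.seed(seed)
  teeth <- lapply(seq_len(n_teeth), function(i) {
    g <- growth_model(crown_length = 36,
                      growth_rate = 0.08 * runif(1, 0.9, 1.1))
    simulate_tooth_series(
      schedule = fodder_schedule(pulse = pulse),
      growth = g,
      start_day = 90 + round(rnorm(1, 0, 10)),
      tooth_id = paste0("T", i),
      seed = seed * 100 + i)$series
  })
  do.call(rbind, teeth)
}
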