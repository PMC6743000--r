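toy_collagen <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:10),
    CN_ratio = c(3.2, 2.8, 3.6, 2.9, 3.7, 3.1, 3.3, NA, 3.0, 3.5),
    pct_C = c(40, 40, 40, 40, 40, 10, 40, 40, 50, 40),
    pct_N = c(14, 14, 14, 14, 14, 14, 4, 14, 14, 14))
}

test_that("QC filter matches hand enumeration with first-failing reasons", {
  rep <- qc_filter(toy_collagen())
  # hand enumeration: accepted s01, s04 (2.9 inclusive), s03 (3.6
  # inclusive), s10; rejected s02 CN_low, s05 CN_high, s06 pctC, s07 pctN,
  # s08 missing, s09 pctC
  expect_equal(rep$accepted$sample_id, c("s01", "s03", "s04", "s10"))
  expect_equal(nrow(rep$accepted) + nrow(rep$rejected), 10)
  expect_equal(
    rep$rejected$reason[match(c("s02", "s05", "s06", "s07", "s08", "s09"),
                              rep$rejected$sample_id)],
    c("CN_low", "CN_high", "pctC_range", "pctN_range", "missing_field",
      "pctC_range"))
  expect_length(intersect(rep$accepted$sample_id, rep$rejected$sample_id), 0)
})

test_that("QC is idempotent, order-invariant and handles empty input", {
  tab <- toy_collagen()
  rep1 <- qc_filter(tab)
  rep2 <- qc_filter(rep1$accepted)
  expect_equal(rep1$accepted, rep2$accepted)
  shuffled <- tab[c(7, 2, 9, 1, 10, 3, 5, 4, 8, 6), ]
  expect_setequal(qc_filter(shuffled)$accepted$sample_id,
                  rep1$accepted$sample_id)
  empty <- qc_filter(tab[0, ])
  expect_equal(nrow(empty$accepted), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("Pearson test equals the direct covariance formula and t transform", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  res <- pearson_test(x, y)
  r_direct <- pearson_r_oracle(x, y)
  expect_equal(res$r, r_direct)
  tstat <- r_direct * sqrt(2 / (1 - r_direct^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), df = 2))
  expect_equal(res$n, 4)
  # perfect linear relation
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(pearson_test(1:2, 1:2))
})

test_that("Mann-Whitney U equals exhaustive pair enumeration, with ties", {
  cases <- list(list(a = c(4, 5), b = c(1, 2, 3)),        # U = 6, all pairs
                list(a = 1, b = 1),                       # single tie, U = 0.5
                list(a = c(2, 2, 3), b = c(1, 2, 4)),
                list(a = rnorm(12), b = rnorm(9)))
  set.seed(44)
  for (cs in cases) {
    res <- mann_whitney_u(cs$a, cs$b)
    expect_equal(res$U, mwu_exact_oracle(cs$a, cs$b))
    # U + U' = n_a * n_b
    res_rev <- mann_whitney_u(cs$b, cs$a)
    expect_equal(res$U + res_rev$U, length(cs$a) * length(cs$b))
    expect_true(res$p > 0 && res$p <= 1)
  }
  expect_equal(mann_whitney_u(c(4, 5), c(1, 2, 3))$U, 6)
})

test_that("lifetime C4 fraction delegates to the mixing model on spacing-corrected values", {
  # boundary identification needs informative data: tight sources and
  # repeat observations pin the posterior to the end-member
  tight <- list(c3 = diet_source("C3_steppe", -24, 0.3),
                c4 = diet_source("C4_millet", -12, 0.3))
  low <- lifetime_c4_fraction(rep(tight$c3$mean + 5, 5), tight,
                              engine = "grid")
  expect_lt(low$p_mean, 0.05)
  high <- lifetime_c4_fraction(rep(tight$c4$mean + 5, 5), tight,
                               engine = "grid")
  expect_gt(high$p_mean, 0.95)
  expect_equal(low$group, "lifetime")
  # equals a direct call on the converted value
  src <- default_sources()
  direct <- posterior_c4_fraction(-16 - 5, src, engine = "grid")
  expect_equal(lifetime_c4_fraction(-16, src, engine = "grid")$p_mean,
               direct$p_mean)
})

test_that("group contrast reports explicit-direction mean/median differences", {
  tab <- data.frame(status = rep(c("livestock", "wild"), c(6, 4)),
                    d15N_col = c(8, 9, 10, 9, 8, 10, 5, 6, 5, 6))
  gc <- group_contrast(tab, "status", "d15N_col")
  expect_equal(gc$summary$n, c(6, 4))
  expect_equal(gc$contrast$mean_diff, mean(tab$d15N_col[1:6]) -
                 mean(tab$d15N_col[7:10]))
  expect_equal(gc$contrast$median_diff, 9 - 5.5)
  # identical groups -> zero difference
  tab2 <- data.frame(status = rep(c("livestock", "wild"), each = 3),
                     d15N_col = rep(c(7, 8, 9), 2))
  expect_equal(group_contrast(tab2, "status", "d15N_col")$contrast$mean_diff, 0)
  expect_error(group_contrast(tab, "habitat", "d15N_col"), "unknown grouping")
})

test_that("synthetic manuring population yields the ~4 permil livestock-wild d15N contrast", {
  spec <- data.frame(
    group = c("lv", "wd"), taxon = c("Ovis aries", "Cervus elaphus"),
    status = c("livestock", "wild"), n = c(150, 20),
    diet_d13C_mean = c(-22, -24), diet_d13C_sd = c(1.5, 1),
    d15N_mean = c(6, 6), d15N_sd = c(1.3, 1.3))
  pop <- simulate_collagen_population(spec, manure_shift = 4, seed = 17)
  gc <- group_contrast(pop$samples, "status", "d15N_col")
  expect_equal(gc$contrast$mean_diff, 4, tolerance = 1)
  expect_equal(gc$contrast$median_diff, 4, tolerance = 1.2)
})

test_that("human C4-consumer flagging applies the -16 permil threshold", {
  tab <- data.frame(status = c("human", "human", "wild"),
                    d13C_col = c(-14.5, -18, -14))
  flagged <- flag_c4_consumers(tab)
  expect_equal(nrow(flagged), 2)
  expect_equal(flagged$c4_consumer, c(TRUE, FALSE))
})
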