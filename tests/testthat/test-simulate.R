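test_that("constant C3 diet with zero noise gives a flat d13C series at the spaced value", {
  sim <- simulate_tooth_series(
    schedule = fodder_schedule(baseline = 0, pulse = 0),
    sources = list(c3 = diet_source("C3_steppe", -24, 1.2),
                   c4 = diet_source("C4_millet", -12, 0.5)),
    noise = noise_model(0, 0, 0, 0))
  expect_equal(sim$series$d13C_apa, rep(-24 + 14.1, nrow(sim$series)),
               tolerance = 1e-12)
  # d18O is an exact (attenuated) sampled cosine: residuals of the exact
  # model class are zero
  env <- seasonal_environment()
  fit <- fit_seasonal_cosine(sim$series)
  expect_lt(fit$rmse, 1e-9)
})

test_that("band count, ordering and determinism invariants hold", {
  g <- growth_model(crown_length = 33.7, growth_rate = 0.08, band_width = 1)
  sim1 <- simulate_tooth_series(growth = g, seed = 11)
  sim2 <- simulate_tooth_series(growth = g, seed = 11)
  sim3 <- simulate_tooth_series(growth = g, seed = 12)
  expect_identical(sim1, sim2)
  expect_false(identical(sim1$series$d13C_apa, sim3$series$d13C_apa))
  expect_equal(nrow(sim1$series), floor(33.7 / 1))
  # bands ordered crown -> cervix: positions strictly decreasing
  expect_true(all(diff(sim1$series$position_mm) < 0))
  expect_true(all(sim1$truth$day_true >= 0 & sim1$truth$day_true < 365))
})

test_that("winter-pulse d13C excess matches the maturation-kernel convolution oracle", {
  sched <- fodder_schedule(baseline = 0, pulse = 0.6,
                           pulse_start = 305, pulse_length = 120)
  growth <- growth_model()
  sim <- simulate_tooth_series(schedule = sched, growth = growth,
                               noise = noise_model(0, 0, 0, 0))
  src <- default_sources()
  diet_fun <- function(day) {
    p <- schedule_fraction(sched, day)
    p * src$c4$mean + (1 - p) * src$c3$mean
  }
  t_form <- (growth$crown_length - sim$truth$position_mm) / growth$growth_rate
  expected <- 14.1 + convolve_schedule_oracle(diet_fun, 90 + t_form,
                                              growth$maturation_window)
  expect_equal(sim$series$d13C_apa, expected, tolerance = 1e-9)
  # the winter maximum exceeds the summer minimum by the oracle-derived gap
  expect_equal(max(sim$series$d13C_apa) - min(sim$series$d13C_apa),
               max(expected) - min(expected), tolerance = 1e-9)
  expect_gt(max(expected) - min(expected), 3)
})

test_that("simulator rejects degenerate growth configurations", {
  expect_error(simulate_tooth_series(
    growth = growth_model(crown_length = 5, growth_rate = 0.08)),
    "less than one")
  expect_error(growth_model(growth_rate = -1))
  expect_error(simulate_tooth_series(
    growth = growth_model(crown_length = 10, growth_rate = 0.08,
                          maturation_window = 200)),
    "maturation window")
})

test_that("collagen population recovers the manuring d15N shift and null effect", {
  spec <- data.frame(
    group = c("livestock", "wild"),
    taxon = c("Ovis aries", "Cervus elaphus"),
    status = c("livestock", "wild"),
    n = c(150, 20),
    diet_d13C_mean = c(-22, -24), diet_d13C_sd = c(1.5, 1),
    d15N_mean = c(6, 6), d15N_sd = c(1.2, 1.2))

  # null: no manuring, group means differ by ~0 (within 3 standard errors)
  pop0 <- simulate_collagen_population(spec, manure_shift = 0, seed = 5)
  m0 <- tapply(pop0$samples$d15N_col, pop0$samples$status, mean)
  se <- sqrt(1.2^2 / 150 + 1.2^2 / 20)
  expect_lt(abs(m0[["livestock"]] - m0[["wild"]]), 3 * se)

  # +4 permil manuring shift recovered within Monte-Carlo error
  pop4 <- simulate_collagen_population(spec, manure_shift = 4, seed = 5)
  m4 <- tapply(pop4$samples$d15N_col, pop4$samples$status, mean)
  expect_equal(m4[["livestock"]] - m4[["wild"]], 4, tolerance = 3 * se)

  # collagen d13C sits at diet + spacing
  expect_equal(mean(pop0$samples$d13C_col[pop0$samples$status == "wild"]),
               -24 + 5, tolerance = 1)
  expect_error(simulate_collagen_population(spec[0, ]), "nrow")
})

test_that("bad C:N fraction is honoured and QC-detectable", {
  spec <- data.frame(group = "g", taxon = "Ovis aries", status = "livestock",
                     n = 400, diet_d13C_mean = -24, diet_d13C_sd = 1,
                     d15N_mean = 6, d15N_sd = 1)
  pop <- simulate_collagen_population(spec, bad_cn_fraction = 0.25, seed = 3)
  bad <- with(pop$samples, CN_ratio < 2.9 | CN_ratio > 3.6)
  expect_equal(mean(bad), 0.25, tolerance = 0.08)
  pop0 <- simulate_collagen_population(spec, bad_cn_fraction = 0, seed = 3)
  expect_true(all(pop0$samples$CN_ratio >= 2.9 & pop0$samples$CN_ratio <= 3.6))
})

test_that("reference fauna round-trips through spacing inversion", {
  spec <- data.frame(
    taxon = c("Cervus elaphus", "Capra sibirica", "Saiga tatarica"),
    tissue_kind = c("enamel", "collagen", "hair"),
    diet_mean = c(-24, -23.5, -25), diet_sd = c(1, 1, 1),
    n = c(30, 20, 22))
  fauna <- simulate_reference_fauna(spec, analytical_sd = 0, seed = 9)
  tab <- spacing_table()
  # inversion equals per-row subtraction oracle, exactly with zero noise
  recon <- tissue_to_diet(fauna$tissue$d13C_tissue, fauna$tissue$tissue_kind,
                          tab)
  expect_equal(recon, fauna$truth$diet_d13C_true, tolerance = 1e-12)
  # zero-noise single value: -24 diet + 14.1 enamel spacing = -9.9
  one <- simulate_reference_fauna(
    data.frame(taxon = "x", tissue_kind = "enamel", diet_mean = -24,
               diet_sd = 0, n = 1), analytical_sd = 0)
  expect_equal(one$tissue$d13C_tissue, -9.9)
  expect_error(simulate_reference_fauna(
    data.frame(taxon = "x", tissue_kind = "antler", diet_mean = -24,
               diet_sd = 1, n = 2)), "unknown tissue kind")
})

test_that("simulated mtDNA reads embed primers and round-trip to their taxa", {
  panel <- simulate_haplotype_panel(seed = 21)
  reads <- simulate_mtdna_reads(panel, c("Ovis aries" = 3,
                                         "Capra sibirica" = 2),
                                mutations = 0, seed = 22)
  expect_equal(nrow(reads$reads), 5)
  # trimming recovers the insert exactly
  ins <- trim_primers(reads$reads$sequence[1])
  expect_identical(ins, panel$sequence[panel$taxon == "Ovis aries"])
  # 0-mutation reads classify back to truth, unambiguously
  calls <- classify_reads(reads$reads, panel)
  expect_identical(calls$taxon, reads$truth$taxon)
  expect_true(all(calls$mismatches == 0))
  expect_true(all(!calls$ambiguous))
  expect_true(all(calls$margin >= 1))
  expect_error(simulate_mtdna_reads(panel, c("Ovis aries" = 1),
                                    mutations = 200), "mutations")
})
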