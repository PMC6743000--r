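#' Winter-pulse fodder schedule
#'
#' Describes the C4 (millet) fraction of the diet as a periodic function of
#' day of year. Days follow the Julian-day convention used throughout the
#' package: day 0 is January 15th and the cycle has period 365. The default
#' pulse runs from day 305 (mid-November) for 120 days (to mid-March),
#' matching a winter-foddering regime in which harvested millet is fed while
#' animals are off pasture.
#'
#' @param baseline C4 dietary fraction outside the pulse, in `[0, 1]`.
#' @param pulse C4 dietary fraction during the pulse, in `[0, 1]`.
#' @param pulse_start first day of the pulse (day of year, 0 = Jan 15).
#' @param pulse_length pulse duration in days, in `[0, 365]`.
#' @return An object of class `fodder_schedule`.
#' @seealso [schedule_fraction()] to evaluate the schedule.
#' @export
fodder_schedule <- function(baseline = 0, pulse = 0.5,
                            pulse_start = 305, pulse_length = 120) {
  stopifnot(is.numeric(baseline), length(baseline) == 1L,
            baseline >= 0, baseline <= 1,
            is.numeric(pulse), length(pulse) == 1L, pulse >= 0, pulse <= 1,
            is.numeric(pulse_start), length(pulse_start) == 1L,
            is.numeric(pulse_length), length(pulse_length) == 1L,
            pulse_length >= 0, pulse_length <= 365)
  structure(list(baseline = baseline, pulse = pulse,
                 pulse_start = pulse_start %% 365,
                 pulse_length = pulse_length),
            class = "fodder_schedule")
}

#' Evaluate a fodder schedule
#'
#' @param schedule a [fodder_schedule()].
#' @param day numeric vector of days; reduced modulo 365, so any real value
#'   (including negative) is accepted.
#' @return C4 dietary fractions in `[0, 1]`, same length as `day`.
#' @export
schedule_fraction <- function(schedule, day) {
  stopifnot(inherits(schedule, "fodder_schedule"))
  d <- day %% 365
  # distance (mod 365) from pulse start; inside pulse iff < pulse_length
  offset <- (d - schedule$pulse_start) %% 365
  ifelse(offset < schedule$pulse_length, schedule$pulse, schedule$baseline)
}

#' Linear tooth-crown growth model
#'
#' Crown growth is modelled as linear in time (constant mm/day); enamel
#' maturation averages the dietary input over a window centred on each
#' band's deposition day. A centred uniform window keeps the smoothed
#' seasonal signal in phase with the environment, so day-of-year assignment
#' from the fitted cosine is unbiased.
#'
#' @param crown_length crown length in mm.
#' @param growth_rate growth rate in mm/day.
#' @param maturation_window maturation averaging window in days.
#' @param band_width sampled band width in mm (default 1, matching 1 mm
#'   sampling bands).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(crown_length = 36, growth_rate = 0.08,
                         maturation_window = 90, band_width = 1) {
  stopifnot(crown_length > 0, growth_rate > 0,
            maturation_window > 0, band_width > 0)
  structure(list(crown_length = crown_length, growth_rate = growth_rate,
                 maturation_window = maturation_window,
                 band_width = band_width),
            class = "growth_model")
}

#' Seasonal d18O environment
#'
#' A 365-day cosine for the oxygen isotope composition recorded in enamel:
#' `d18O(t) = mean + amplitude * cos(2 * pi * (t - peak_day) / 365)`, with
#' `t` a day of year (0 = Jan 15) and the maximum anchored at `peak_day`
#' (default 182, mid-July).
#'
#' @param mean_d18O annual mean d18O (permil VPDB).
#' @param amplitude seasonal amplitude (permil, >= 0).
#' @param peak_day day of year of the d18O maximum (0 = Jan 15).
#' @return An object of class `seasonal_environment`.
#' @export
seasonal_environment <- function(mean_d18O = -8, amplitude = 2,
                                 peak_day = 182) {
  stopifnot(amplitude >= 0)
  structure(list(mean_d18O = mean_d18O, amplitude = amplitude,
                 peak_day = peak_day %% 365),
            class = "seasonal_environment")
}

environment_d18O <- function(environment, day) {
  environment$mean_d18O + environment$amplitude *
    cos(2 * pi * (day - environment$peak_day) / 365)
}

#' Analytical noise model
#'
#' Gaussian analytical noise at the measurement precisions of the isotope
#' channels: 0.05 permil for enamel carbon, 0.07 permil for enamel oxygen,
#' 0.1 permil for collagen carbon and 0.2 permil for collagen nitrogen.
#'
#' @param sd_d13C_apa,sd_d18O_apa,sd_d13C_col,sd_d15N_col standard
#'   deviations in permil, all `>= 0`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_d13C_apa = 0.05, sd_d18O_apa = 0.07,
                        sd_d13C_col = 0.1, sd_d15N_col = 0.2) {
  sds <- c(sd_d13C_apa, sd_d18O_apa, sd_d13C_col, sd_d15N_col)
  stopifnot(all(is.finite(sds)), all(sds >= 0))
  structure(list(sd_d13C_apa = sd_d13C_apa, sd_d18O_apa = sd_d18O_apa,
                 sd_d13C_col = sd_d13C_col, sd_d15N_col = sd_d15N_col),
            class = "noise_model")
}

#' Diet-tissue spacing table
#'
#' Systematic permil offsets between diet and consumer tissue d13C,
#' subtracted from tissue values to recover dietary values. Defaults are
#' standard isotope-ecology values: +14.1 for enamel bioapatite, +5.0 for
#' bone collagen, +3.2 for hair; all overridable.
#'
#' @param enamel,collagen,hair spacing in permil for each tissue kind.
#' @param ... further named tissue kinds with their spacings.
#' @return A named numeric vector of class `spacing_table`.
#' @export
spacing_table <- function(enamel = 14.1, collagen = 5.0, hair = 3.2, ...) {
  extra <- c(...)
  tab <- c(enamel = enamel, collagen = collagen, hair = hair, extra)
  stopifnot(all(is.finite(tab)), !anyDuplicated(names(tab)),
            all(nzchar(names(tab))))
  structure(tab, class = "spacing_table")
}

spacing_for <- function(table, tissue_kind) {
  stopifnot(inherits(table, "spacing_table"))
  missing_kind <- setdiff(unique(tissue_kind), names(table))
  if (length(missing_kind)) {
    stop("unknown tissue kind: ", paste(missing_kind, collapse = ", "))
  }
  unname(table[tissue_kind])
}

#' Dietary end-member (source) distribution
#'
#' @param name source name, e.g. `"C3_steppe"` or `"C4_millet"`.
#' @param mean mean dietary d13C (permil VPDB).
#' @param sd standard deviation (permil, > 0).
#' @param n number of records contributing to the estimate (optional).
#' @return An object of class `diet_source`.
#' @export
diet_source <- function(name, mean, sd, n = NA_integer_) {
  stopifnot(is.character(name), nzchar(name), is.finite(mean),
            is.finite(sd), sd > 0)
  structure(list(name = name, mean = mean, sd = sd, n = n),
            class = "diet_source")
}

#' Default C3/C4 dietary sources
#'
#' The C3 steppe end-member summarises wild-herbivore dietary d13C values of
#' -26 to -22 permil (mean -24, sd 1.2); the C4 millet end-member clusters
#' at -12 permil (sd 0.5). The ~12 permil separation far exceeds four times
#' the larger source sd, so the two-source mixture is identifiable.
#'
#' @return A list with components `c3` and `c4`, each a [diet_source()].
#' @export
default_sources <- function() {
  list(c3 = diet_source("C3_steppe", -24, 1.2),
       c4 = diet_source("C4_millet", -12, 0.5))
}

check_sources <- function(sources) {
  stopifnot(is.list(sources), inherits(sources$c3, "diet_source"),
            inherits(sources$c4, "diet_source"))
  if (sources$c4$mean <= sources$c3$mean) {
    stop("sources not separable: C4 mean must exceed C3 mean")
  }
  invisible(sources)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
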