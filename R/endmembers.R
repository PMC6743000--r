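#' Convert tissue d13C to dietary d13C
#'
#' Subtracts the diet-tissue spacing for each tissue kind, recovering the
#' dietary d13C value recorded by the tissue.
#'
#' @param value numeric vector of tissue d13C values (permil VPDB).
#' @param tissue_kind character vector (recycled) naming the tissue of each
#'   value; must appear in `table`.
#' @param table a [spacing_table()].
#' @return Dietary d13C values (permil VPDB), same length as `value`.
#' @export
tissue_to_diet <- function(value, tissue_kind, table = spacing_table()) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  if (length(tissue_kind) == 1L) tissue_kind <- rep(tissue_kind, length(value))
  stopifnot(length(tissue_kind) == length(value))
  value - spacing_for(table, tissue_kind)
}

#' Build C3 and C4 source distributions from reference values
#'
#' Summarises reference-fauna dietary d13C values (the local C3 steppe
#' end-member) and millet d13C values (the C4 end-member) into the two
#' source distributions used by the mixing model. Sample standard
#' deviations use the n-1 denominator; a floor avoids degenerate
#' likelihoods when a source happens to be near-constant.
#'
#' @param reference_diet_values numeric vector of dietary d13C values from
#'   wild/reference herbivores (C3 end-member), length >= 2.
#' @param millet_values numeric vector of millet d13C values (C4
#'   end-member), length >= 2.
#' @param sd_floor minimum source sd in permil (default 0.3).
#' @return A list with components `c3` and `c4`, each a [diet_source()].
#' @export
build_source_distributions <- function(reference_diet_values, millet_values,
                                       sd_floor = 0.3) {
  stopifnot(length(reference_diet_values) >= 2, length(millet_values) >= 2,
            all(is.finite(reference_diet_values)),
            all(is.finite(millet_values)), sd_floor >= 0)
  m3 <- mean(reference_diet_values)
  m4 <- mean(millet_values)
  if (m3 >= m4) stop("sources not separable: C3 mean must be below C4 mean")
  sources <- list(
    c3 = diet_source("C3_steppe", m3,
                     max(stats::sd(reference_diet_values), sd_floor),
                     length(reference_diet_values)),
    c4 = diet_source("C4_millet", m4,
                     max(stats::sd(millet_values), sd_floor),
                     length(millet_values)))
  check_sources(sources)
}
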