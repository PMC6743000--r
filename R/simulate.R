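# Forward simulators for every input the pipeline consumes, each with known
# ground truth retained alongside the analysis-facing table.

# Uniform moving average of f(day) centred on day t, discretised at ~1-day
# resolution. Symmetric offsets keep a cosine input exactly cosine-shaped
# (attenuated in amplitude, unchanged in phase).
smooth_days <- function(f, t, window) {
  m <- max(1L, as.integer(round(window)))
  offsets <- (seq_len(m) - (m + 1) / 2) * (window / m)
  vapply(t, function(tt) mean(f(tt + offsets)), numeric(1))
}

#' Simulate an intra-tooth isotope series
#'
#' Forward-simulates sequential enamel-band d13C and d18O measurements for
#' one tooth. The crown grows linearly from tip to cervix; each 1 mm band's
#' d13C records the maturation-window average of the dietary mixture
#' `p(t) * muC4 + (1 - p(t)) * muC3` plus the enamel diet-tissue spacing,
#' and its d18O records the window-averaged seasonal cosine. Analytical
#' noise is added at the stated precisions. True deposition days and diet
#' fractions are returned separately from the analysis-facing table.
#'
#' @param schedule a [fodder_schedule()] giving the C4 fraction by day.
#' @param growth a [growth_model()]; the crown must span at least one full
#'   year and at least one maturation window.
#' @param environment a [seasonal_environment()] for d18O.
#' @param sources C3/C4 [diet_source()] pair as from [default_sources()].
#' @param spacing a [spacing_table()]; the `enamel` entry is used.
#' @param noise a [noise_model()]; set sds to 0 for noiseless output.
#' @param start_day day of year (0 = Jan 15) when crown formation starts.
#' @param tooth_id,specimen,taxon,site,period,molar identifier columns
#'   copied into the output table.
#' @param seed integer seed for the noise draws, or `NULL`.
#' @return A list with `series` (data frame: tooth_id, specimen, taxon,
#'   site, period, molar, position_mm, d13C_apa, d18O_apa; bands ordered
#'   crown to cervix, positions in mm from cervix) and `truth` (data frame:
#'   band, position_mm, day_true, p_day, p_smoothed, d13C_true, d18O_true).
#' @export
simulate_tooth_series <- function(schedule = fodder_schedule(),
                                  growth = growth_model(),
                                  environment = seasonal_environment(),
                                  sources = default_sources(),
                                  spacing = spacing_table(),
                                  noise = noise_model(),
                                  start_day = 90,
                                  tooth_id = "T1", specimen = "S1",
                                  taxon = "Ovis aries", site = "SIM",
                                  period = "SIM", molar = "M2",
                                  seed = NULL) {
  stopifnot(inherits(schedule, "fodder_schedule"),
            inherits(growth, "growth_model"),
            inherits(environment, "seasonal_environment"),
            inherits(noise, "noise_model"))
  check_sources(sources)
  duration <- growth$crown_length / growth$growth_rate
  if (duration < growth$maturation_window) {
    stop("crown formation spans less than one maturation window")
  }
  if (duration < 365) {
    stop("crown formation spans less than one full year")
  }

  n_bands <- floor(growth$crown_length / growth$band_width)
  band <- seq_len(n_bands)
  # band 1 is at the crown tip (deposited first); positions in mm from cervix
  position_mm <- growth$crown_length - (band - 0.5) * growth$band_width
  t_form <- (growth$crown_length - position_mm) / growth$growth_rate
  day_true <- (start_day + t_form) %% 365

  diet_fun <- function(day) {
    p <- schedule_fraction(schedule, day)
    p * sources$c4$mean + (1 - p) * sources$c3$mean
  }
  p_smoothed <- smooth_days(function(d) schedule_fraction(schedule, d),
                            start_day + t_form, growth$maturation_window)
  d13C_true <- spacing_for(spacing, "enamel") +
    smooth_days(diet_fun, start_day + t_form, growth$maturation_window)
  d18O_true <- smooth_days(function(d) environment_d18O(environment, d),
                           start_day + t_form, growth$maturation_window)

  noise_c <- with_seed(seed, {
    cbind(stats::rnorm(n_bands, 0, noise$sd_d13C_apa),
          stats::rnorm(n_bands, 0, noise$sd_d18O_apa))
  })

  series <- data.frame(
    tooth_id = tooth_id, specimen = specimen, taxon = taxon,
    site = site, period = period, molar = molar,
    position_mm = position_mm,
    d13C_apa = d13C_true + noise_c[, 1],
    d18O_apa = d18O_true + noise_c[, 2])
  truth <- data.frame(
    band = band, position_mm = position_mm, day_true = day_true,
    p_day = schedule_fraction(schedule, day_true),
    p_smoothed = p_smoothed,
    d13C_true = d13C_true, d18O_true = d18O_true)
  list(series = series, truth = truth, seed = seed)
}

#' Simulate a collagen d13C/d15N population
#'
#' Draws bone-collagen samples for labelled groups (livestock, wild fauna,
#' humans). Collagen d13C is the lifetime-mean dietary d13C plus the
#' collagen diet-tissue spacing; d15N is the group baseline, with a
#' manuring shift added to livestock only (manured millet plots enrich
#' vegetation, and so consumers, in 15N). Biological between-individual
#' spread and analytical noise are both applied. A configurable fraction
#' of samples receives out-of-range C:N ratios to exercise quality control.
#'
#' @param group_spec data frame with columns `group`, `taxon`, `status`
#'   (one of livestock/wild/human), `n`, `diet_d13C_mean`, `diet_d13C_sd`,
#'   `d15N_mean`, `d15N_sd` (sds are biological, permil).
#' @param manure_shift permil added to livestock d15N (default 0).
#' @param spacing a [spacing_table()]; the `collagen` entry is used.
#' @param noise a [noise_model()] for the analytical components.
#' @param bad_cn_fraction fraction of samples given C:N outside the
#'   acceptable 2.9-3.6 range.
#' @param site,period identifier columns copied into the output.
#' @param seed integer seed, or `NULL`.
#' @return A list with `samples` (data frame: sample_id, site, period,
#'   taxon, status, d13C_col, d15N_col, pct_C, pct_N, CN_ratio) and
#'   `truth` (per-sample generating group and dietary mean).
#' @export
simulate_collagen_population <- function(group_spec, manure_shift = 0,
                                         spacing = spacing_table(),
                                         noise = noise_model(),
                                         bad_cn_fraction = 0,
                                         site = "SIM", period = "SIM",
                                         seed = NULL) {
  stopifnot(is.data.frame(group_spec), nrow(group_spec) >= 1)
  needed <- c("group", "taxon", "status", "n", "diet_d13C_mean",
              "diet_d13C_sd", "d15N_mean", "d15N_sd")
  missing_cols <- setdiff(needed, names(group_spec))
  if (length(missing_cols)) {
    stop("group_spec lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(group_spec$n >= 1),
            all(group_spec$status %in% c("livestock", "wild", "human")),
            bad_cn_fraction >= 0, bad_cn_fraction <= 1)

  with_seed(seed, {
    rows <- lapply(seq_len(nrow(group_spec)), function(i) {
      g <- group_spec[i, ]
      n <- g$n
      shift <- if (g$status == "livestock") manure_shift else 0
      diet <- stats::rnorm(n, g$diet_d13C_mean, g$diet_d13C_sd)
      d13C <- diet + spacing_for(spacing, "collagen") +
        stats::rnorm(n, 0, noise$sd_d13C_col)
      d15N <- stats::rnorm(n, g$d15N_mean + shift, g$d15N_sd) +
        stats::rnorm(n, 0, noise$sd_d15N_col)
      bad <- stats::runif(n) < bad_cn_fraction
      cn <- ifelse(bad,
                   ifelse(stats::runif(n) < 0.5,
                          stats::runif(n, 2.4, 2.89),
                          stats::runif(n, 3.61, 4.3)),
                   stats::runif(n, 2.95, 3.55))
      data.frame(group = g$group, taxon = g$taxon, status = g$status,
                 d13C_col = d13C, d15N_col = d15N,
                 pct_C = stats::rnorm(n, 41, 2),
                 pct_N = stats::rnorm(n, 14.5, 0.8),
                 CN_ratio = cn, diet_d13C_true = diet)
    })
    tab <- do.call(rbind, rows)
    tab$sample_id <- sprintf("C%03d", seq_len(nrow(tab)))
    samples <- data.frame(sample_id = tab$sample_id, site = site,
                          period = period, taxon = tab$taxon,
                          status = tab$status, d13C_col = tab$d13C_col,
                          d15N_col = tab$d15N_col, pct_C = tab$pct_C,
                          pct_N = tab$pct_N, CN_ratio = tab$CN_ratio)
    truth <- data.frame(sample_id = tab$sample_id, group = tab$group,
                        diet_d13C_true = tab$diet_d13C_true)
    list(samples = samples, truth = truth, seed = seed)
  })
}

#' Simulate reference-fauna tissue values
#'
#' Generates tissue d13C values for reference taxa whose diets sample the
#' local vegetation: tissue value = dietary value + diet-tissue spacing +
#' analytical noise. Inverting through [tissue_to_diet()] recovers the
#' generating dietary distribution, mirroring how wild herbivore tissues
#' are used to reconstruct the C3 steppe end-member.
#'
#' @param taxa_spec data frame with columns `taxon`, `tissue_kind`,
#'   `diet_mean`, `diet_sd`, `n`. Every `tissue_kind` must appear in
#'   `spacing`.
#' @param spacing a [spacing_table()].
#' @param analytical_sd analytical noise sd in permil (default 0.1).
#' @param seed integer seed, or `NULL`.
#' @return A list with `tissue` (data frame: sample_id, taxon, tissue_kind,
#'   d13C_tissue) and `truth` (per-sample generating dietary value).
#' @export
simulate_reference_fauna <- function(taxa_spec, spacing = spacing_table(),
                                     analytical_sd = 0.1, seed = NULL) {
  stopifnot(is.data.frame(taxa_spec), nrow(taxa_spec) >= 1,
            all(c("taxon", "tissue_kind", "diet_mean", "diet_sd", "n")
                %in% names(taxa_spec)),
            all(taxa_spec$n >= 1))
  spacing_for(spacing, taxa_spec$tissue_kind)  # rejects unknown kinds

  with_seed(seed, {
    rows <- lapply(seq_len(nrow(taxa_spec)), function(i) {
      g <- taxa_spec[i, ]
      diet <- stats::rnorm(g$n, g$diet_mean, g$diet_sd)
      data.frame(taxon = g$taxon, tissue_kind = g$tissue_kind,
                 d13C_tissue = diet + spacing_for(spacing, g$tissue_kind) +
                   stats::rnorm(g$n, 0, analytical_sd),
                 diet_d13C_true = diet)
    })
    tab <- do.call(rbind, rows)
    tab$sample_id <- sprintf("R%03d", seq_len(nrow(tab)))
    list(tissue = tab[c("sample_id", "taxon", "tissue_kind", "d13C_tissue")],
         truth = tab[c("sample_id", "taxon", "diet_d13C_true")],
         seed = seed)
  })
}

#' Simulate a cytochrome-b haplotype panel
#'
#' Builds a synthetic labelled reference panel of equal-length MT-CYB
#' fragments: a random ancestral fragment is mutated independently for each
#' taxon so that taxa differ at roughly `divergence` sites.
#'
#' @param taxa data frame with columns `taxon` and `status`
#'   (domestic/wild); one panel entry is produced per row.
#' @param fragment_length fragment length in bp (default 110, the amplified
#'   MT-CYB stretch).
#' @param divergence number of substitutions separating each taxon from the
#'   shared ancestral fragment.
#' @param seed integer seed, or `NULL`.
#' @return A `haplotype_panel` data frame (columns id, taxon, status,
#'   sequence).
#' @export
simulate_haplotype_panel <- function(taxa = data.frame(
                                       taxon = c("Ovis aries", "Ovis ammon",
                                                 "Capra hircus",
                                                 "Capra sibirica"),
                                       status = c("domestic", "wild",
                                                  "domestic", "wild")),
                                     fragment_length = 110, divergence = 5,
                                     seed = NULL) {
  stopifnot(is.data.frame(taxa), nrow(taxa) >= 1,
            all(c("taxon", "status") %in% names(taxa)),
            divergence < fragment_length)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ancestor <- sample(bases, fragment_length, replace = TRUE)
    seqs <- vapply(seq_len(nrow(taxa)), function(i) {
      s <- ancestor
      pos <- sample.int(fragment_length, divergence)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
      paste(s, collapse = "")
    }, character(1))
    panel <- data.frame(id = sprintf("hap%02d", seq_len(nrow(taxa))),
                        taxon = taxa$taxon, status = taxa$status,
                        sequence = seqs)
    class(panel) <- c("haplotype_panel", "data.frame")
    panel
  })
}

#' Simulate amplicon reads from a haplotype panel
#'
#' Constructs reads as forward primer + haplotype fragment (with the stated
#' number of random substitutions) + reverse complement of the reverse
#' primer, retaining truth labels for round-trip classification tests.
#'
#' @param panel a `haplotype_panel` as from [simulate_haplotype_panel()] or
#'   [read_haplotype_panel()].
#' @param counts named integer vector: reads per taxon (names must match
#'   panel taxa).
#' @param mutations substitutions introduced per read (must be smaller than
#'   the fragment length).
#' @param primers list with `forward` and `reverse` primer strings, as from
#'   [default_primers()].
#' @param seed integer seed, or `NULL`.
#' @return A list with `reads` (data frame: read_id, sequence) and `truth`
#'   (read_id, taxon, status).
#' @export
simulate_mtdna_reads <- function(panel, counts, mutations = 0,
                                 primers = default_primers(), seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), nrow(panel) >= 1,
            is.numeric(counts), !is.null(names(counts)),
            all(names(counts) %in% panel$taxon),
            mutations < min(nchar(panel$sequence)))
  bases <- c("A", "C", "G", "T")
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  with_seed(seed, {
    rows <- lapply(names(counts), function(tx) {
      hap <- panel$sequence[match(tx, panel$taxon)]
      status <- panel$status[match(tx, panel$taxon)]
      reads <- vapply(seq_len(counts[[tx]]), function(k) {
        s <- strsplit(hap, "")[[1]]
        if (mutations > 0) {
          pos <- sample.int(length(s), mutations)
          for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
        }
        paste0(primers$forward, paste(s, collapse = ""), rc(primers$reverse))
      }, character(1))
      data.frame(taxon = tx, status = status, sequence = reads)
    })
    tab <- do.call(rbind, rows)
    tab$read_id <- sprintf("read%03d", seq_len(nrow(tab)))
    list(reads = tab[c("read_id", "sequence")],
         truth = tab[c("read_id", "taxon", "status")],
         seed = seed)
  })
}
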