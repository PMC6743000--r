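# Quality screening and comparative statistics for bone-collagen
# d13C/d15N data.

#' Quality-screen collagen samples
#'
#' Accepts samples whose atomic C:N ratio lies in `[2.9, 3.6]` and whose
#' %C and %N fall within established screening ranges (inclusive bounds).
#' Each rejected sample carries its first failing reason in the order
#' missing_field, CN_low, CN_high, pctC_range, pctN_range. Deterministic
#' and idempotent; row order never affects the accepted set.
#'
#' @param samples data frame with columns `CN_ratio`, `pct_C`, `pct_N`
#'   (plus any identifier columns, which are carried through).
#' @param cn_range acceptable atomic C:N interval (default `c(2.9, 3.6)`).
#' @param pctC_range,pctN_range acceptable %C and %N intervals (defaults
#'   `c(15.3, 47)` and `c(5.5, 17.3)`, standard published screening
#'   ranges).
#' @return An object of class `qc_report`: `accepted` and `rejected` data
#'   frames (rejected rows gain a `reason` column); their union is the
#'   input and they are disjoint.
#' @export
qc_filter <- function(samples, cn_range = c(2.9, 3.6),
                      pctC_range = c(15.3, 47), pctN_range = c(5.5, 17.3)) {
  stopifnot(is.data.frame(samples),
            all(c("CN_ratio", "pct_C", "pct_N") %in% names(samples)))
  n <- nrow(samples)
  reason <- rep(NA_character_, n)
  if (n) {
    cn <- samples$CN_ratio
    pc <- samples$pct_C
    pn <- samples$pct_N
    miss <- !is.finite(cn) | !is.finite(pc) | !is.finite(pn)
    reason[is.na(reason) & miss] <- "missing_field"
    reason[is.na(reason) & cn < cn_range[1]] <- "CN_low"
    reason[is.na(reason) & cn > cn_range[2]] <- "CN_high"
    reason[is.na(reason) & (pc < pctC_range[1] | pc > pctC_range[2])] <-
      "pctC_range"
    reason[is.na(reason) & (pn < pctN_range[1] | pn > pctN_range[2])] <-
      "pctN_range"
  }
  rejected <- samples[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  structure(list(accepted = samples[is.na(reason), , drop = FALSE],
                 rejected = rejected,
                 thresholds = list(cn = cn_range, pct_C = pctC_range,
                                   pct_N = pctN_range)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Collagen QC: %d accepted, %d rejected\n",
              nrow(x$accepted), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    print(table(x$rejected$reason))
  }
  invisible(x)
}

#' Pearson product-moment correlation test
#'
#' Two-sided test of association between paired isotope series (e.g.
#' d13C_col vs d15N_col within a site-period group); the p-value uses the
#' t transform with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors without missing values, length >= 3.
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups, oriented so that
#' `U = #\{(i, j): a_i > b_j\} + 0.5 * #ties` counts pairs in which the
#' first group (by convention, livestock) exceeds the second (wild fauna).
#' The p-value uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param a,b numeric vectors (first argument = livestock by convention).
#' @return A list: `U`, `p`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = FALSE, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # degenerate all-tied comparison carries no evidence
  list(U = unname(wt$statistic), p = p,
       n_a = length(a), n_b = length(b))
}

#' Lifetime C4 dietary fraction from a collagen d13C value
#'
#' Converts a collagen d13C value to dietary d13C via the collagen
#' diet-tissue spacing and estimates the lifetime C4 fraction with the
#' mixing model ("lifetime" group).
#'
#' @param d13C_col collagen d13C value(s) in permil; multiple values are
#'   treated as repeat observations of one lifetime group.
#' @param sources C3/C4 [diet_source()] pair.
#' @param spacing a [spacing_table()]; the `collagen` entry is used.
#' @param ... passed to [posterior_c4_fraction()].
#' @return A `mix_result` for the `"lifetime"` group.
#' @export
lifetime_c4_fraction <- function(d13C_col, sources = default_sources(),
                                 spacing = spacing_table(), ...) {
  diet <- tissue_to_diet(d13C_col, "collagen", spacing)
  posterior_c4_fraction(diet, sources = sources, group = "lifetime", ...)
}

#' Group summary statistics and contrast
#'
#' Per-group n, mean, median and sd of an isotope value, plus the
#' difference of means and of medians between two named groups (first
#' minus second, direction explicit in the output).
#'
#' @param samples data frame of collagen samples.
#' @param grouping name of the grouping column (e.g. `"status"` or
#'   `"period"`).
#' @param value name of the value column (e.g. `"d15N_col"`).
#' @param contrast character vector of two group levels to contrast
#'   (default `c("livestock", "wild")`), or `NULL` for summaries only.
#' @return A list: `summary` (data frame per group) and `contrast` (data
#'   frame with the mean and median differences), or `NULL` contrast.
#' @export
group_contrast <- function(samples, grouping = "status",
                           value = "d15N_col",
                           contrast = c("livestock", "wild")) {
  stopifnot(is.data.frame(samples))
  if (!grouping %in% names(samples)) stop("unknown grouping field: ", grouping)
  if (!value %in% names(samples)) stop("unknown value field: ", value)
  g <- factor(samples[[grouping]])
  v <- samples[[value]]
  summ <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(v, g, mean)),
    median = as.numeric(tapply(v, g, stats::median)),
    sd = as.numeric(tapply(v, g, stats::sd)))
  ctr <- NULL
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2)
    if (!all(contrast %in% levels(g))) {
      stop("contrast groups absent: ",
           paste(setdiff(contrast, levels(g)), collapse = ", "))
    }
    i <- match(contrast, summ$group)
    ctr <- data.frame(
      contrast = paste(contrast, collapse = " - "),
      mean_diff = summ$mean[i[1]] - summ$mean[i[2]],
      median_diff = summ$median[i[1]] - summ$median[i[2]])
  }
  list(summary = summ, contrast = ctr)
}

#' Flag probable C4-consuming humans
#'
#' Descriptive threshold flagging of human collagen values indicating
#' substantial millet consumption (default threshold: d13C_col >= -16
#' permil, a documented heuristic).
#'
#' @param samples data frame with columns `status` and `d13C_col`.
#' @param threshold flagging threshold in permil.
#' @return The human rows of `samples` with a logical `c4_consumer`
#'   column.
#' @export
flag_c4_consumers <- function(samples, threshold = -16) {
  stopifnot(is.data.frame(samples),
            all(c("status", "d13C_col") %in% names(samples)))
  humans <- samples[samples$status == "human", , drop = FALSE]
  humans$c4_consumer <- humans$d13C_col >= threshold
  humans
}
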