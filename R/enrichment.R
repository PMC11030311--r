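#' Case/control per-individual rate ratio
#'
#' The average per-individual variant rate in cases divided by that in
#' controls. The confidence interval and p-value come from a binomial test of
#' the case/control split of the pooled variant count, with the null
#' proportion set by the cohort-size offset; the binomial CI on the case share
#' is transformed back to the rate-ratio scale. With zero control variants the
#' ratio is infinite and the interval one-sided.
#'
#' @param case_count,control_count Variant counts in each cohort (after any
#'   stratum filter).
#' @param case_n,control_n Number of individuals per cohort.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `case_count`, `control_count`, `rr`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
rate_ratio <- function(case_count, control_count, case_n, control_n,
                       conf_level = 0.95) {
  stopifnot(case_n > 0, control_n > 0, case_count >= 0, control_count >= 0)
  total <- case_count + control_count
  p0 <- case_n / (case_n + control_n)
  to_rr <- function(p) (p / (1 - p)) * (control_n / case_n)
  if (total == 0) {
    return(tibble::tibble(case_count, control_count, rr = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          p_value = NA_real_))
  }
  bt <- stats::binom.test(case_count, total, p = p0,
                          conf.level = conf_level)
  tibble::tibble(
    case_count = case_count,
    control_count = control_count,
    rr = (case_count / case_n) / (control_count / control_n),
    ci_lower = to_rr(bt$conf.int[1]),
    ci_upper = to_rr(bt$conf.int[2]),
    p_value = bt$p.value
  )
}

#' Odds ratio of case vs control variants in the top score percentile
#'
#' Pools case and control variants scored by one predictor, ranks them, and
#' forms the 2x2 table of (top pct% vs rest) x (case vs control). The odds
#' ratio is the sample cross-product ratio; the p-value is Fisher's exact
#' test. Variants tied with the percentile boundary score are all included in
#' the top set. Unscored variants (NA) are excluded.
#'
#' @param case_scores,control_scores Predictor scores; larger = more
#'   deleterious.
#' @param pct Top percentile (default 10).
#' @param conf_level Confidence level for the (log-)OR interval.
#' @return A one-row tibble: the 2x2 cells `top_case`, `top_control`,
#'   `rest_case`, `rest_control`, plus `or`, `ci_lower`, `ci_upper`,
#'   `p_value`.
#' @export
top_percentile_or <- function(case_scores, control_scores, pct = 10,
                              conf_level = 0.95) {
  case_scores <- case_scores[!is.na(case_scores)]
  control_scores <- control_scores[!is.na(control_scores)]
  pooled <- c(case_scores, control_scores)
  k <- ceiling(length(pooled) * pct / 100)
  if (k < 1) {
    stop("`pct` selects fewer than one variant", call. = FALSE)
  }
  thr <- sort(pooled, decreasing = TRUE)[k]
  a <- sum(case_scores >= thr)
  b <- sum(control_scores >= thr)
  c_ <- sum(case_scores < thr)
  d <- sum(control_scores < thr)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, conf.level = conf_level)
  log_or_se <- sqrt(sum(1 / pmax(tab, 0.5)))
  or <- (a * d) / max(b * c_, .Machine$double.xmin)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    top_case = a, top_control = b, rest_case = c_, rest_control = d,
    or = or,
    ci_lower = exp(log(max(or, .Machine$double.xmin)) - z * log_or_se),
    ci_upper = exp(log(max(or, .Machine$double.xmin)) + z * log_or_se),
    p_value = ft$p.value
  )
}

#' Per-bin case/control rate ratios over local OE
#'
#' Applies [rate_ratio()] within bins of local missense OE (left-closed,
#' right-open; the final bin is open-ended), e.g. to ask whether de novo
#' variants in cases concentrate in the most constrained regions.
#'
#' @param case,control Lists with elements `n_individuals` (count) and
#'   `variants` (data frame with a `local_oe` column), as produced by
#'   [simulate_cohorts()].
#' @param breaks Bin edges over local OE (default `seq(0, 1, 0.2)`); values at
#'   or above the last edge fall in the final bin.
#' @return A tibble with one row per bin: `bin`, `oe_lo`, `oe_hi`,
#'   case/control counts and the rate-ratio columns; bins with no variants in
#'   either cohort have `NA` statistics.
#' @export
oe_bin_enrichment <- function(case, control, breaks = seq(0, 1, 0.2)) {
  check_columns(case$variants, "local_oe", "case$variants")
  check_columns(control$variants, "local_oe", "control$variants")
  nb <- length(breaks) - 1
  bin_of <- function(oe) {
    pmin(nb, findInterval(oe, breaks))
  }
  counts <- function(v) {
    tabulate(bin_of(v$local_oe), nbins = nb)
  }
  cc <- counts(case$variants)
  kc <- counts(control$variants)
  purrr::map_dfr(seq_len(nb), function(b) {
    rr <- rate_ratio(cc[b], kc[b], case$n_individuals, control$n_individuals)
    dplyr::bind_cols(
      tibble::tibble(bin = b, oe_lo = breaks[b],
                     oe_hi = if (b < nb) breaks[b + 1] else Inf),
      rr
    )
  })
}
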