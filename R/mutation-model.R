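#' Fit a plateau calibration model
#'
#' Calibrates raw per-context mutation rates against the proportion of possible
#' variants of that context actually observed at (putatively neutral) sites in
#' the reference cohort. The fit is ordinary least squares of proportion
#' observed on the raw rate `mu`; separate fits are intended per chromosome
#' class (autosomal/pseudoautosomal, chrX, chrY) and CpG status, since CpG
#' transitions saturate at large cohort sizes.
#'
#' @param proportions A data frame with columns `context`, `alt`,
#'   `methyl_level` and `prop_observed` (proportion of possible variants of
#'   that context observed).
#' @param rates A mutation-rate table with columns `context`, `alt`,
#'   `methyl_level`, `mu` (per-generation rate, > 0).
#' @param model_class One of `"autosomal"`, `"chrX"`, `"chrY"` (metadata).
#' @param cpg_status One of `"CpG"`, `"non-CpG"` (metadata).
#'
#' @return An object of class `plateau_model` with elements `slope`,
#'   `intercept`, `model_class`, `cpg_status`, `n`.
#' @export
fit_plateau <- function(proportions, rates,
                        model_class = c("autosomal", "chrX", "chrY"),
                        cpg_status = c("non-CpG", "CpG")) {
  model_class <- match.arg(model_class)
  cpg_status <- match.arg(cpg_status)
  check_rates(rates)
  need <- c("context", "alt", "methyl_level", "prop_observed")
  check_columns(proportions, need, "proportions")

  df <- dplyr::inner_join(
    proportions, rates,
    by = c("context", "alt", "methyl_level")
  )
  if (nrow(df) < 2 || dplyr::n_distinct(df$mu) < 2) {
    stop("plateau fit needs at least 2 distinct (mu, proportion) pairs",
         call. = FALSE)
  }
  fit <- stats::lm(prop_observed ~ mu, data = df)
  structure(
    list(
      slope = unname(stats::coef(fit)[["mu"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      model_class = model_class,
      cpg_status = cpg_status,
      n = nrow(df)
    ),
    class = "plateau_model"
  )
}

#' @export
print.plateau_model <- function(x, ...) {
  cat(sprintf(
    "Plateau model (%s, %s): prop = %.4g + %.4g * mu  [n = %d]\n",
    x$model_class, x$cpg_status, x$intercept, x$slope, x$n
  ))
  invisible(x)
}

#' @param x A `plateau_model`.
#' @param ... Unused.
#' @rdname fit_plateau
#' @method tidy plateau_model
#' @export
tidy.plateau_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "mu"),
    estimate = c(x$intercept, x$slope)
  )
}

#' Predict the calibrated proportion observed for raw rates
#'
#' Predictions are clamped to `[0, 1]`: the linear fit can exit the unit
#' interval at extreme mutation rates, but the quantity is a proportion.
#'
#' @param object A `plateau_model`.
#' @param mu Raw mutation rates.
#' @param clamp Clamp predictions to the unit interval (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of calibrated proportions.
#' @export
predict.plateau_model <- function(object, mu, clamp = TRUE, ...) {
  p <- object$intercept + object$slope * mu
  if (clamp) p <- pmin(1, pmax(0, p))
  p
}

#' Fit the low-coverage correction model
#'
#' The scaling factor is the total number of observed synonymous variants
#' divided by the total neutral expectation mass (possible synonymous variants
#' weighted by their aggregated mutation rate). Optionally, a depth-dependent
#' linear model on log10(median coverage) is fitted over depth strata below the
#' coverage threshold, for use as a smoother correction than the single factor.
#'
#' @param observed_synonymous Total observed synonymous count.
#' @param mu_sum Total expectation mass (sum of rates over possible synonymous
#'   variants); must be > 0.
#' @param depth_table Optional data frame with columns `coverage`, `observed`,
#'   `mu_sum` giving per-depth-stratum counts; rows with coverage below
#'   `low_coverage_threshold` are used to fit
#'   `observed/mu_sum ~ log10(coverage)`.
#' @param low_coverage_threshold Median depth below which the correction
#'   applies (default 40).
#' @param form `"scaling"` (single factor, default) or `"loglinear"`
#'   (depth-dependent; requires `depth_table`).
#'
#' @return An object of class `coverage_model` with elements `scaling_factor`,
#'   `low_coverage_threshold`, `form` and, for the log-linear form,
#'   `coefficients` (intercept, slope on log10 depth).
#' @export
fit_coverage_scaling <- function(observed_synonymous, mu_sum,
                                 depth_table = NULL,
                                 low_coverage_threshold = 40,
                                 form = c("scaling", "loglinear")) {
  form <- match.arg(form)
  if (!is.numeric(mu_sum) || mu_sum <= 0) {
    stop("`mu_sum` must be positive", call. = FALSE)
  }
  out <- list(
    scaling_factor = observed_synonymous / mu_sum,
    low_coverage_threshold = low_coverage_threshold,
    form = form,
    coefficients = NULL
  )
  if (form == "loglinear") {
    if (is.null(depth_table)) {
      stop("`form = \"loglinear\"` requires `depth_table`", call. = FALSE)
    }
    check_columns(depth_table, c("coverage", "observed", "mu_sum"),
                  "depth_table")
    low <- dplyr::filter(depth_table,
                         .data$coverage > 0,
                         .data$coverage < low_coverage_threshold)
    if (nrow(low) < 2) {
      stop("need at least 2 depth strata below the threshold", call. = FALSE)
    }
    low <- dplyr::mutate(low,
                         ratio = .data$observed / .data$mu_sum,
                         log_cov = log10(.data$coverage))
    fit <- stats::lm(ratio ~ log_cov, data = low)
    out$coefficients <- c(
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      slope = unname(stats::coef(fit)[["log_cov"]])
    )
  }
  structure(out, class = "coverage_model")
}

#' @export
print.coverage_model <- function(x, ...) {
  cat(sprintf("Coverage model (%s): scaling factor %.4g, threshold %dx\n",
              x$form, x$scaling_factor, as.integer(x$low_coverage_threshold)))
  if (!is.null(x$coefficients)) {
    cat(sprintf("  log10-depth correction: %.4g + %.4g * log10(coverage)\n",
                x$coefficients[["intercept"]], x$coefficients[["slope"]]))
  }
  invisible(x)
}

coverage_correction <- function(model, coverage) {
  corr <- rep(1, length(coverage))
  low <- coverage > 0 & coverage < model$low_coverage_threshold
  if (!any(low)) return(corr)
  if (model$form == "scaling" || is.null(model$coefficients)) {
    corr[low] <- model$scaling_factor
  } else {
    pred <- model$coefficients[["intercept"]] +
      model$coefficients[["slope"]] * log10(coverage[low])
    corr[low] <- pmin(1, pmax(0, pred))
  }
  corr
}

#' Per-site adjusted mutation expectation (mu_adj)
#'
#' Looks up each site's raw context rate, applies the plateau calibration, and
#' applies the low-coverage correction to sites with median coverage strictly
#' below the coverage model's threshold. Sites at or above the threshold are
#' never coverage-corrected. Sites with zero coverage should be excluded
#' upstream (they are not observable).
#'
#' @param sites A site table with columns `context`, `alt`, `methyl_level`,
#'   `coverage`.
#' @param rates Mutation-rate table (`context`, `alt`, `methyl_level`, `mu`).
#' @param plateau A `plateau_model`.
#' @param coverage A `coverage_model`.
#'
#' @return The input tibble with an added (or replaced) `mu_adj` column.
#' @export
compute_mu_adj <- function(sites, rates, plateau, coverage) {
  check_rates(rates)
  check_columns(sites, c("context", "alt", "methyl_level", "coverage"),
                "sites")
  cov_model <- coverage
  joined <- dplyr::left_join(
    dplyr::select(sites, -dplyr::any_of(c("mu", "mu_adj"))),
    rates,
    by = c("context", "alt", "methyl_level")
  )
  if (anyNA(joined$mu)) {
    bad <- unique(joined$context[is.na(joined$mu)])
    stop("no mutation rate for context(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  joined$mu_adj <- predict(plateau, joined$mu) *
    coverage_correction(cov_model, joined$coverage)
  joined %>%
    dplyr::select(-"mu") %>%
    tibble::as_tibble()
}

#' Expected variant count over a set of sites
#'
#' The neutral expectation is additive: the expected count of any site set is
#' the sum of its per-site `mu_adj` contributions. An empty set has
#' expectation 0.
#'
#' @param sites A data frame carrying a `mu_adj` column.
#' @return A single number.
#' @export
expected_count <- function(sites) {
  if (nrow(sites) == 0) return(0)
  check_columns(sites, "mu_adj", "sites")
  sum(sites$mu_adj)
}

check_rates <- function(rates) {
  check_columns(rates, c("context", "alt", "methyl_level", "mu"), "rates")
  if (any(rates$mu <= 0)) stop("mutation rates must be positive", call. = FALSE)
  invisible(rates)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("`%s` is missing required column(s): %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
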