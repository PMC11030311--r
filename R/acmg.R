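#' Local posterior probability of pathogenicity along a score
#'
#' Estimates, at each point of a score grid, the probability that a variant
#' with that score is pathogenic, from a labeled variant set. The estimate at
#' a grid point is the proportion pathogenic among the k labeled variants
#' nearest in score, converted to the target prior via an odds adjustment
#' (the labeled set's own prevalence rarely equals the clinical prior).
#' One-sided 95% bootstrap bounds (variant resampling, seeded) accompany each
#' point: the lower bound is the stringent side for pathogenic evidence, the
#' upper bound for benign evidence. Grid points whose window cannot gather k
#' labeled variants are marked undefined rather than extrapolated.
#'
#' @param scores Numeric score per labeled variant (e.g. MCR OE, MPC).
#' @param labels Binary labels: 1 = pathogenic (P/LP), 0 = benign (B/LB).
#' @param grid Evaluation points; default an even grid of 41 points over the
#'   score range.
#' @param k Window size: number of nearest labeled variants per grid point
#'   (default 100).
#' @param prior Prior probability of pathogenicity (default 0.0441, the
#'   canonical value of the point-based classification framework).
#' @param n_bootstrap Bootstrap replicates for the confidence bounds
#'   (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `posterior_curve`: a tibble with columns
#'   `score`, `posterior`, `ci_lower`, `ci_upper`, `n_window`; attributes
#'   `prior`, `k`, `seed`.
#' @export
local_posterior <- function(scores, labels, grid = NULL, k = 100,
                            prior = 0.0441, n_bootstrap = 200, seed = 1) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- labels[ok]
  if (is.null(grid)) {
    grid <- seq(min(scores), max(scores), length.out = 41)
  }
  grid <- sort(grid)
  if (k > length(scores)) {
    stop("window size `k` exceeds the number of labeled variants",
         call. = FALSE)
  }
  sample_prev <- mean(labels)

  point <- knn_posterior(scores, labels, grid, k, prior, sample_prev)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(length(scores), replace = TRUE)
      knn_posterior(scores[idx], labels[idx], grid, k, prior, sample_prev)
    }, numeric(length(grid)))
  })
  ci_lower <- apply(boots, 1, stats::quantile, probs = 0.05, na.rm = TRUE)
  ci_upper <- apply(boots, 1, stats::quantile, probs = 0.95, na.rm = TRUE)

  out <- tibble::tibble(
    score = grid,
    posterior = point,
    ci_lower = pmax(0, pmin(ci_lower, point)),
    ci_upper = pmin(1, pmax(ci_upper, point)),
    n_window = ifelse(is.na(point), 0L, k)
  )
  structure(out, prior = prior, k = k, seed = seed,
            class = c("posterior_curve", class(out)))
}

# k-nearest-neighbor local proportion pathogenic, prior-adjusted on the odds
# scale from the sample prevalence to the target prior.
knn_posterior <- function(scores, labels, grid, k, prior, sample_prev) {
  ord <- order(scores)
  s <- scores[ord]
  l <- labels[ord]
  cum <- c(0, cumsum(l))
  n <- length(s)
  vapply(grid, function(g) {
    # window [lo, lo+k-1] of sorted scores minimizing the max distance to g
    idx <- findInterval(g, s)
    lo <- max(1L, min(idx - k %/% 2L, n - k + 1L))
    # slide the window toward g while it reduces the span's max distance
    repeat {
      if (lo > 1 && abs(s[lo + k - 1L] - g) > abs(s[lo - 1L] - g)) {
        lo <- lo - 1L
      } else if (lo + k <= n && abs(s[lo] - g) > abs(s[lo + k] - g)) {
        lo <- lo + 1L
      } else {
        break
      }
    }
    p_hat <- (cum[lo + k] - cum[lo]) / k
    adjust_prior(p_hat, sample_prev, prior)
  }, 0)
}

# Convert a local proportion measured at sample prevalence to the posterior at
# the target prior, on the odds scale.
adjust_prior <- function(p, sample_prev, prior) {
  if (sample_prev <= 0 || sample_prev >= 1) return(p)
  lr <- (p / (1 - p)) / (sample_prev / (1 - sample_prev))  # local LR+
  post_odds <- lr * prior / (1 - prior)
  ifelse(is.infinite(lr), 1, post_odds / (1 + post_odds))
}

#' @export
print.posterior_curve <- function(x, ...) {
  cat(sprintf("Local posterior curve: %d grid points, k = %d, prior = %.4f\n",
              nrow(x), attr(x, "k"), attr(x, "prior")))
  NextMethod()
}

#' Posterior cutoffs of the point-based evidence framework
#'
#' Converts the framework's odds of pathogenicity for very strong evidence
#' (`c`) and its 1/2, 1/4 and 1/8 roots (strong, moderate, supporting) into
#' posterior probability cutoffs at a given prior; the benign-direction
#' cutoffs use the reciprocal odds.
#'
#' @param prior Prior probability of pathogenicity.
#' @param c Odds of pathogenicity for very strong evidence (default 350).
#' @return A tibble: `strength`, `direction`, `odds`, `posterior_cutoff`.
#' @export
posterior_cutoffs <- function(prior = 0.0441, c = 350) {
  if (prior <= 0 || prior >= 1) stop("`prior` must be in (0,1)", call. = FALSE)
  strengths <- c("supporting", "moderate", "strong", "very strong")
  expo <- c(1 / 8, 1 / 4, 1 / 2, 1)
  odds_p <- c^expo
  to_post <- function(o) {
    po <- o * prior / (1 - prior)
    po / (1 + po)
  }
  dplyr::bind_rows(
    tibble::tibble(strength = strengths, direction = "pathogenic",
                   odds = odds_p, posterior_cutoff = to_post(odds_p)),
    tibble::tibble(strength = strengths, direction = "benign",
                   odds = 1 / odds_p, posterior_cutoff = to_post(1 / odds_p))
  )
}

#' Score thresholds meeting ACMG/AMP evidence strengths
#'
#' For each evidence strength, finds the most permissive score whose
#' confidence bound (the stringent side of the local posterior) meets the
#' strength's posterior cutoff: for pathogenic evidence the lower bound must
#' reach at least the cutoff, for benign evidence the upper bound must stay at
#' or below it. Strengths never met are reported as `NA` ("not reached").
#' Using the bound rather than the point estimate can only make thresholds
#' more conservative.
#'
#' @param curve A [local_posterior()] curve.
#' @param prior Prior probability of pathogenicity (default: the curve's).
#' @param c Point-scale constant (default 350).
#' @param low_is_pathogenic Score orientation: `TRUE` when smaller scores mean
#'   stronger pathogenic evidence (e.g. OE), `FALSE` for scores like MPC.
#' @param use_ci Use the stringent confidence bound (default `TRUE`); `FALSE`
#'   thresholds on the point estimate.
#' @return An object of class `evidence_thresholds`: a tibble with columns
#'   `strength`, `direction`, `posterior_cutoff`, `score_cutoff` (NA when not
#'   reached); attribute `prior`.
#' @export
evidence_thresholds <- function(curve, prior = attr(curve, "prior"), c = 350,
                                low_is_pathogenic = TRUE, use_ci = TRUE) {
  cuts <- posterior_cutoffs(prior, c)
  path_stat <- if (use_ci) curve$ci_lower else curve$posterior
  ben_stat <- if (use_ci) curve$ci_upper else curve$posterior
  cutoff_for <- function(cutoff, direction) {
    if (direction == "pathogenic") {
      ok <- !is.na(path_stat) & path_stat >= cutoff
      if (!any(ok)) return(NA_real_)
      # most permissive score still meeting the cutoff
      if (low_is_pathogenic) max(curve$score[ok]) else min(curve$score[ok])
    } else {
      ok <- !is.na(ben_stat) & ben_stat <= cutoff
      if (!any(ok)) return(NA_real_)
      if (low_is_pathogenic) min(curve$score[ok]) else max(curve$score[ok])
    }
  }
  cuts$score_cutoff <- mapply(cutoff_for, cuts$posterior_cutoff,
                              cuts$direction)
  structure(tibble::as_tibble(cuts), prior = prior,
            class = c("evidence_thresholds", class(tibble::tibble())))
}

#' @export
print.evidence_thresholds <- function(x, ...) {
  cat(sprintf("ACMG/AMP evidence thresholds (prior %.4f)\n", attr(x, "prior")))
  NextMethod()
}
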