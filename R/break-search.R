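#' Search configuration for the breakpoint scan
#'
#' @param min_expected Minimum expected missense count each subsection created
#'   by a split must retain (default 16). Prevents splits that would create
#'   tiny subsections with unstable OE estimates.
#' @param alpha Significance level of the likelihood-ratio test (default
#'   0.001).
#' @param df_single,df_double Degrees of freedom of the chi-square reference
#'   for the one-break (one extra OE parameter) and two-break (two extra)
#'   tests. Defaults 1 and 2 give critical values 10.83 and 13.82 at
#'   alpha = 0.001.
#' @return A list of class `search_config`.
#' @export
search_config <- function(min_expected = 16, alpha = 0.001,
                          df_single = 1, df_double = 2) {
  stopifnot(min_expected > 0, alpha > 0, alpha < 1)
  structure(
    list(
      min_expected = min_expected,
      alpha = alpha,
      df_single = df_single,
      df_double = df_double,
      crit_single = stats::qchisq(1 - alpha, df_single),
      crit_double = stats::qchisq(1 - alpha, df_double)
    ),
    class = "search_config"
  )
}

# Poisson log-likelihood with the factorial term dropped (it cancels in the
# ratio). 0 * log(0) is defined as 0: a section with no observed variants and
# rate 0 contributes nothing.
pois_ll <- function(obs, lambda) {
  term <- obs * log(lambda)
  term[obs == 0] <- 0
  term - lambda
}

chi_sq_sections <- function(obs, exp) {
  oe_null <- oe_ratio(sum(obs), sum(exp))
  oe_alt <- oe_ratio(obs, exp)
  ll0 <- sum(pois_ll(obs, exp * oe_null))
  ll1 <- sum(pois_ll(obs, exp * oe_alt))
  2 * (ll1 - ll0)
}

#' Likelihood-ratio statistic for splitting an interval into two sections
#'
#' Under the null, both sections share the interval-wide capped OE; under the
#' alternative each section has its own capped OE. The statistic is
#' chi-square = 2(ln p1 - ln p0), where p0 and p1 are the products of Poisson
#' likelihoods of the section counts at rates exp * OE under each model.
#' Because each capped OE maximizes its section's Poisson likelihood over
#' [0, 1], p1 >= p0 and the statistic is non-negative.
#'
#' @param obs_a,exp_a Observed count and expectation of section A.
#' @param obs_b,exp_b Observed count and expectation of section B.
#' @return An object of class `split_stat`: list with `chi_sq`, `df`,
#'   `sections` (tibble of per-section obs/exp/oe), `positions` (NA here; set
#'   by the scan functions).
#' @examples
#' chi_sq_two_section(2, 20, 20, 20)$chi_sq  # ~17.09
#' chi_sq_two_section(10, 20, 5, 10)$chi_sq  # 0: both OEs equal the pooled OE
#' @export
chi_sq_two_section <- function(obs_a, exp_a, obs_b, exp_b) {
  stopifnot(exp_a > 0, exp_b > 0, obs_a >= 0, obs_b >= 0)
  obs <- c(obs_a, obs_b)
  exp <- c(exp_a, exp_b)
  new_split_stat(chi_sq_sections(obs, exp), obs, exp, df = 1)
}

#' Likelihood-ratio statistic for splitting an interval into three sections
#'
#' Three-section analog of [chi_sq_two_section()], used by the simultaneous
#' two-break scan.
#'
#' @param obs_a,exp_a,obs_b,exp_b,obs_c,exp_c Per-section observed counts and
#'   expectations.
#' @return A `split_stat` with `df = 2`.
#' @export
chi_sq_three_section <- function(obs_a, exp_a, obs_b, exp_b, obs_c, exp_c) {
  stopifnot(exp_a > 0, exp_b > 0, exp_c > 0)
  obs <- c(obs_a, obs_b, obs_c)
  exp <- c(exp_a, exp_b, exp_c)
  new_split_stat(chi_sq_sections(obs, exp), obs, exp, df = 2)
}

new_split_stat <- function(chi_sq, obs, exp, df, positions = NA_real_) {
  structure(
    list(
      chi_sq = chi_sq,
      df = df,
      positions = positions,
      sections = tibble::tibble(
        section = LETTERS[seq_along(obs)],
        obs = obs,
        exp = exp,
        oe = oe_ratio(obs, exp)
      )
    ),
    class = "split_stat"
  )
}

#' @export
print.split_stat <- function(x, ...) {
  cat(sprintf("Split statistic: chi-square %.4f (df %d)", x$chi_sq, x$df))
  if (!all(is.na(x$positions))) {
    cat(" at position(s)", paste(x$positions, collapse = ", "))
  }
  cat("\n")
  print(x$sections)
  invisible(x)
}

#' @param x A `split_stat`.
#' @param ... Unused.
#' @rdname chi_sq_two_section
#' @method tidy split_stat
#' @export
tidy.split_stat <- function(x, ...) {
  dplyr::mutate(x$sections, chi_sq = x$chi_sq, df = x$df)
}

# Vectorized two-section statistic over candidate break indices.
# obs_a/exp_a etc. are vectors (one entry per candidate break).
chi_sq_two_vec <- function(obs_a, exp_a, obs_b, exp_b) {
  oe0 <- oe_ratio(obs_a + obs_b, exp_a + exp_b)
  ll0 <- pois_ll(obs_a, exp_a * oe0) + pois_ll(obs_b, exp_b * oe0)
  ll1 <- pois_ll(obs_a, exp_a * oe_ratio(obs_a, exp_a)) +
    pois_ll(obs_b, exp_b * oe_ratio(obs_b, exp_b))
  2 * (ll1 - ll0)
}

chi_sq_three_vec <- function(obs_a, exp_a, obs_b, exp_b, obs_c, exp_c) {
  oe0 <- oe_ratio(obs_a + obs_b + obs_c, exp_a + exp_b + exp_c)
  ll0 <- pois_ll(obs_a, exp_a * oe0) + pois_ll(obs_b, exp_b * oe0) +
    pois_ll(obs_c, exp_c * oe0)
  ll1 <- pois_ll(obs_a, exp_a * oe_ratio(obs_a, exp_a)) +
    pois_ll(obs_b, exp_b * oe_ratio(obs_b, exp_b)) +
    pois_ll(obs_c, exp_c * oe_ratio(obs_c, exp_c))
  2 * (ll1 - ll0)
}

# Section sums over position-index range [i, j] of a transcript_model,
# via cumulative arrays.
range_obs <- function(tm, i, j) {
  tm$cum_obs[j] - if (i > 1) tm$cum_obs[i - 1] else 0
}
range_exp <- function(tm, i, j) {
  tm$cum_exp[j] - if (i > 1) tm$cum_exp[i - 1] else 0
}

#' Scan an interval for the best single breakpoint
#'
#' Evaluates the two-section likelihood-ratio statistic at every eligible
#' coding position of the interval (a position is eligible when both resulting
#' subsections keep at least `min_expected` expected missense variants) and
#' returns the maximal split if it is significant at `alpha` with `df_single`
#' degrees of freedom. A breakpoint at position k assigns positions <= k to
#' the left section (closed-left convention). When several positions tie at
#' the maximum, the leftmost is returned.
#'
#' @param tm A `transcript_model`.
#' @param config A [search_config()].
#' @param lo,hi Position-index bounds of the subsection scanned (defaults:
#'   whole transcript).
#' @return A `split_stat` with `positions` set (cds position of the break), or
#'   `NULL` if no position is eligible or none is significant.
#' @export
scan_single_break <- function(tm, config = search_config(),
                              lo = 1L, hi = length(tm$positions)) {
  n <- hi - lo + 1
  if (n < 2) return(NULL)
  ks <- lo:(hi - 1)  # break after index k
  base_exp <- if (lo > 1) tm$cum_exp[lo - 1] else 0
  exp_a <- tm$cum_exp[ks] - base_exp
  exp_b <- range_exp(tm, lo, hi) - exp_a
  elig <- exp_a >= config$min_expected & exp_b >= config$min_expected
  if (!any(elig)) return(NULL)
  ks <- ks[elig]
  exp_a <- exp_a[elig]
  exp_b <- exp_b[elig]
  obs_a <- tm$cum_obs[ks] - if (lo > 1) tm$cum_obs[lo - 1] else 0
  obs_b <- range_obs(tm, lo, hi) - obs_a
  chi <- chi_sq_two_vec(obs_a, exp_a, obs_b, exp_b)
  best <- which.max(chi)  # which.max returns the first (leftmost) maximum
  if (chi[best] <= config$crit_single) return(NULL)
  st <- new_split_stat(chi[best],
                       c(obs_a[best], obs_b[best]),
                       c(exp_a[best], exp_b[best]),
                       df = config$df_single,
                       positions = tm$positions[ks[best]])
  st$break_index <- ks[best]
  st
}

#' Scan an interval for the best pair of simultaneous breakpoints
#'
#' Exhaustively evaluates the three-section statistic over every ordered pair
#' of positions whose three resulting subsections each keep at least
#' `min_expected` expected variants, and returns the maximal pair if
#' significant at `alpha` with `df_double` degrees of freedom. Run when the
#' single-break scan found nothing. Ties broken toward the lexicographically
#' smallest (leftmost) pair.
#'
#' @inheritParams scan_single_break
#' @return A `split_stat` with two `positions`, or `NULL`.
#' @export
scan_two_breaks <- function(tm, config = search_config(),
                            lo = 1L, hi = length(tm$positions)) {
  n <- hi - lo + 1
  if (n < 3) return(NULL)
  total_exp <- range_exp(tm, lo, hi)
  if (total_exp < 3 * config$min_expected) return(NULL)
  base_obs <- if (lo > 1) tm$cum_obs[lo - 1] else 0
  base_exp <- if (lo > 1) tm$cum_exp[lo - 1] else 0
  total_obs <- range_obs(tm, lo, hi)

  best_chi <- -Inf
  best <- NULL
  for (i in lo:(hi - 2)) {
    exp_a <- tm$cum_exp[i] - base_exp
    if (exp_a < config$min_expected) next
    if (total_exp - exp_a < 2 * config$min_expected) break
    obs_a <- tm$cum_obs[i] - base_obs
    js <- (i + 1):(hi - 1)
    exp_b <- tm$cum_exp[js] - tm$cum_exp[i]
    exp_c <- total_exp - exp_a - exp_b
    elig <- exp_b >= config$min_expected & exp_c >= config$min_expected
    if (!any(elig)) next
    js <- js[elig]
    exp_b <- exp_b[elig]
    exp_c <- exp_c[elig]
    obs_b <- tm$cum_obs[js] - tm$cum_obs[i]
    obs_c <- total_obs - obs_a - obs_b
    chi <- chi_sq_three_vec(obs_a, exp_a, obs_b, exp_b, obs_c, exp_c)
    k <- which.max(chi)
    if (chi[k] > best_chi) {
      best_chi <- chi[k]
      best <- list(i = i, j = js[k],
                   obs = c(obs_a, obs_b[k], obs_c),
                   exp = c(exp_a, exp_b[k], exp_c))
    }
  }
  if (is.null(best) || best_chi <= config$crit_double) return(NULL)
  st <- new_split_stat(best_chi, best$obs, best$exp,
                       df = config$df_double,
                       positions = tm$positions[c(best$i, best$j)])
  st$break_index <- c(best$i, best$j)
  st
}

#' Recursive breakpoint search over a transcript
#'
#' Applies the single-break scan; if no significant single break exists, the
#' simultaneous two-break scan; splits at the winning position(s); and recurses
#' into each new subsection as if it were an independent transcript, until no
#' further significant break is found. The result is an ordered set of
#' missense constraint regions (MCRs) that partition the transcript's coding
#' positions.
#'
#' @param tm A `transcript_model`.
#' @param config A [search_config()].
#' @return A tibble of regions: `transcript_id`, `region_index`, `cds_start`,
#'   `cds_end` (1-based inclusive; internal boundaries follow the closed-left
#'   convention), `obs`, `exp`, `oe`, `chi_sq` (statistic of the split that
#'   created the region; `NA` for an unsplit transcript),
#'   `n_regions_in_transcript`. A single row means no significant regional
#'   structure.
#' @export
recursive_search <- function(tm, config = search_config()) {
  n <- length(tm$positions)
  segments <- search_segments(tm, config, 1L, n, NA_real_)
  m <- length(segments)
  tibble::tibble(
    transcript_id = tm$transcript_id,
    region_index = seq_len(m),
    cds_start = vapply(seq_len(m), function(r) {
      if (r == 1) tm$positions[1] else tm$positions[segments[[r - 1]]$hi] + 1
    }, 0),
    cds_end = vapply(segments, function(s) {
      if (s$hi == n) tm$positions[n] else tm$positions[s$hi]
    }, 0),
    obs = vapply(segments, function(s) range_obs(tm, s$lo, s$hi), 0),
    exp = vapply(segments, function(s) range_exp(tm, s$lo, s$hi), 0),
    chi_sq = vapply(segments, function(s) s$chi_sq, 0),
    n_regions_in_transcript = m
  ) %>%
    dplyr::mutate(oe = oe_ratio(.data$obs, .data$exp), .before = "chi_sq")
}

# Returns a list of segments (lo, hi index bounds + chi_sq of the creating
# split) partitioning [lo, hi].
search_segments <- function(tm, config, lo, hi, chi_sq) {
  st <- scan_single_break(tm, config, lo, hi)
  if (is.null(st)) st <- scan_two_breaks(tm, config, lo, hi)
  if (is.null(st)) {
    return(list(list(lo = lo, hi = hi, chi_sq = chi_sq)))
  }
  bounds <- c(lo - 1L, st$break_index, hi)
  out <- list()
  for (s in seq_len(length(bounds) - 1)) {
    out <- c(out, search_segments(tm, config,
                                  bounds[s] + 1L, bounds[s + 1L],
                                  st$chi_sq))
  }
  out
}

#' Segment every transcript of a site table into constraint regions
#'
#' Pipe-friendly wrapper: builds a [transcript_model()] per transcript and
#' runs [recursive_search()] on each.
#'
#' @param sites Site table with finalized `observed` flags and `mu_adj`
#'   (columns `transcript_id`, `cds_pos`, `observed`, `mu_adj`).
#' @param config A [search_config()].
#' @return A tibble of regions for all transcripts (see [recursive_search()]).
#' @export
search_regions <- function(sites, config = search_config()) {
  sites %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::group_split() %>%
    purrr::map(~ recursive_search(transcript_model(.x), config)) %>%
    purrr::list_rbind()
}
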