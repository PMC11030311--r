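# Independent oracles, coded directly from the method's printed definitions.
# They share no code with the package internals: Poisson likelihoods come from
# dpois() (factorial terms included; they cancel in the ratio), section sums
# are direct summations, and the scans are naive exhaustive loops.

oracle_cap <- function(obs, exp) min(1, obs / max(exp, 1e-9))

oracle_chi2_two <- function(obs_a, exp_a, obs_b, exp_b) {
  oe <- oracle_cap(obs_a + obs_b, exp_a + exp_b)
  p0 <- dpois(obs_a, exp_a * oe, log = TRUE) +
    dpois(obs_b, exp_b * oe, log = TRUE)
  p1 <- dpois(obs_a, exp_a * oracle_cap(obs_a, exp_a), log = TRUE) +
    dpois(obs_b, exp_b * oracle_cap(obs_b, exp_b), log = TRUE)
  2 * (p1 - p0)
}

oracle_chi2_three <- function(obs_a, exp_a, obs_b, exp_b, obs_c, exp_c) {
  oe <- oracle_cap(obs_a + obs_b + obs_c, exp_a + exp_b + exp_c)
  p0 <- dpois(obs_a, exp_a * oe, log = TRUE) +
    dpois(obs_b, exp_b * oe, log = TRUE) +
    dpois(obs_c, exp_c * oe, log = TRUE)
  p1 <- dpois(obs_a, exp_a * oracle_cap(obs_a, exp_a), log = TRUE) +
    dpois(obs_b, exp_b * oracle_cap(obs_b, exp_b), log = TRUE) +
    dpois(obs_c, exp_c * oracle_cap(obs_c, exp_c), log = TRUE)
  2 * (p1 - p0)
}

# Brute-force single-break argmax over a per-position (obs, exp) table.
# Returns NULL or list(pos_index, chi_sq).
oracle_scan_single <- function(obs, exp, min_expected, crit) {
  n <- length(obs)
  best <- NULL
  for (k in seq_len(n - 1)) {
    ea <- sum(exp[1:k]); eb <- sum(exp[(k + 1):n])
    if (ea < min_expected || eb < min_expected) next
    chi <- oracle_chi2_two(sum(obs[1:k]), ea, sum(obs[(k + 1):n]), eb)
    if (is.null(best) || chi > best$chi_sq) {
      best <- list(pos_index = k, chi_sq = chi)
    }
  }
  if (is.null(best) || best$chi_sq <= crit) return(NULL)
  best
}

# Brute-force ordered-pair enumeration for two simultaneous breaks.
# (Section sums via base cumsum for speed; the statistic itself is still the
# independent dpois-based evaluation.)
oracle_scan_two <- function(obs, exp, min_expected, crit) {
  n <- length(obs)
  co <- cumsum(obs)
  ce <- cumsum(exp)
  best <- NULL
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      ea <- ce[i]; eb <- ce[j] - ce[i]; ec <- ce[n] - ce[j]
      if (ea < min_expected || eb < min_expected || ec < min_expected) next
      chi <- oracle_chi2_three(co[i], ea, co[j] - co[i], eb,
                               co[n] - co[j], ec)
      if (is.null(best) || chi > best$chi_sq) {
        best <- list(pos_index = c(i, j), chi_sq = chi)
      }
    }
  }
  if (is.null(best) || best$chi_sq <= crit) return(NULL)
  best
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over the
# table's support, summing all outcomes no more probable than the observed one
# (the classical definition, with the 1 + 1e-7 relative tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total (white balls)
  n_ <- c + d         # row 2 total (black balls)
  k <- a + c          # column 1 total (drawn)
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  sum(probs[probs <= dhyper(a, m, n_, k) * (1 + 1e-7)])
}

# Random transcript-like per-position tables for oracle-equivalence checks.
random_position_table <- function(n, seed) {
  withr::with_seed(seed, {
    exp <- runif(n, 0.2, 0.6)
    oe <- runif(1, 0.1, 1)
    obs <- rpois(n, exp * oe)
  })
  list(obs = obs, exp = exp)
}

# Wrap a per-position table as the transcript_model the scans consume,
# going through the public constructor.
as_tm <- function(obs, exp, id = "TX") {
  transcript_model(tibble::tibble(
    transcript_id = id,
    cds_pos = seq_along(obs),
    observed = NA,  # placeholder; obs passed via repeated rows below
    mu_adj = exp
  ) %>%
    dplyr::mutate(observed = obs))
}
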