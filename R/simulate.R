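#' Simulation profile for a synthetic transcript
#'
#' Describes the ground truth a simulated transcript is generated from: the
#' number of possible missense positions, the per-site neutral expectation,
#' region boundaries and the true OE of each region, and a coverage
#' distribution.
#'
#' @param n_sites Number of coding positions with a possible missense variant.
#' @param mu Adjusted expectation contribution per possible substitution;
#'   scalar or length `n_sites`. Default 0.4 (large-cohort scale, so a few
#'   hundred positions carry tens of expected variants).
#' @param boundaries Last positions of all regions but the final one (sorted,
#'   within `1..n_sites-1`); `integer(0)` for a single uniform region.
#' @param oes True OE per region, in `[0, 1]`; length `length(boundaries)+1`.
#' @param n_alts Possible missense substitutions per coding position
#'   (default 3, the maximum for a nucleotide site and typical of real site
#'   tables, where most coding positions carry 2-3 possible missense
#'   changes).
#' @return A list of class `sim_profile`.
#' @export
sim_profile <- function(n_sites, mu = 0.4, boundaries = integer(0),
                        oes = 1, n_alts = 3) {
  stopifnot(
    n_sites >= 1,
    length(oes) == length(boundaries) + 1,
    all(oes >= 0 & oes <= 1),
    all(boundaries >= 1 & boundaries < n_sites),
    !is.unsorted(boundaries, strictly = TRUE),
    n_alts >= 1, n_alts <= 3
  )
  structure(
    list(n_sites = n_sites, mu = mu, boundaries = as.integer(boundaries),
         oes = oes, n_alts = as.integer(n_alts)),
    class = "sim_profile"
  )
}

#' Simulate a transcript's possible-site table with planted regions
#'
#' Each possible missense site is observed independently with probability
#' `min(1, true_OE * mu_adj)` of its region — per-site Bernoulli draws, so
#' region totals are Poisson-binomial and, at small per-site rates,
#' approximately Poisson around `OE * expected`, the generative assumption of
#' the segmentation model. Sites are emitted in the same schema the analysis
#' functions read.
#'
#' @param profile A [sim_profile()].
#' @param transcript_id Identifier stamped on the sites.
#' @param seed Integer seed.
#' @param coverage Median depth per site (scalar or vector, default 50).
#' @return A list: `sites` (tibble with `transcript_id`, `cds_pos`, `ref`,
#'   `alt`, `context`, `methyl_level`, `coverage`, `allele_count`,
#'   `allele_freq`, `qc_pass`, `observed`, `mu_adj`) and `truth` (tibble of
#'   region `cds_start`, `cds_end`, `true_oe`).
#' @export
simulate_transcript <- function(profile, transcript_id = "TX1", seed = 1,
                                coverage = 50) {
  stopifnot(inherits(profile, "sim_profile"))
  n <- profile$n_sites
  k <- profile$n_alts
  pos <- rep(seq_len(n), each = k)
  mu <- rep(rep_len(profile$mu, n), each = k)
  bounds <- c(profile$boundaries, n)
  region <- findInterval(pos - 1L, bounds) + 1L
  p <- profile$oes[region] * mu
  if (any(p > 1)) {
    warning("per-site observation probability > 1; clamped", call. = FALSE)
    p <- pmin(1, p)
  }
  observed <- withr::with_seed(seed, stats::runif(n * k) < p)
  sites <- tibble::tibble(
    transcript_id = transcript_id,
    cds_pos = pos,
    ref = "A",
    alt = rep(c("G", "C", "T")[seq_len(k)], n),
    context = "ACA",
    methyl_level = 0L,
    coverage = rep(rep_len(coverage, n), each = k),
    allele_count = ifelse(observed, 1L, 0L),
    allele_freq = ifelse(observed, 1e-5, 0),
    qc_pass = TRUE,
    observed = observed,
    mu_adj = mu
  )
  starts <- c(1L, profile$boundaries + 1L)
  truth <- tibble::tibble(
    cds_start = starts,
    cds_end = bounds,
    true_oe = profile$oes
  )
  list(sites = sites, truth = truth)
}

#' Simulate a labeled variant feature table
#'
#' Draws the six MPC features from class-conditional Gaussians: benign
#' variants from the base distribution, pathogenic variants shifted by
#' `effects` (per-feature mean shifts in SD units). Zero effects give an
#' uninformative training set; a large single-feature shift makes that
#' coefficient dominate a fitted model.
#'
#' @param n_path,n_benign Class sizes.
#' @param effects Named numeric vector of mean shifts for the pathogenic
#'   class; names among [mpc_features()]. Unnamed features shift by 0.
#' @param seed Integer seed.
#' @return A tibble with `variant_id`, `label` (1 = pathogenic) and the six
#'   feature columns; `n_path + n_benign` rows.
#' @export
simulate_labeled_variants <- function(n_path, n_benign,
                                      effects = c(local_oe = -1,
                                                  polyphen2 = 1),
                                      seed = 1) {
  stopifnot(all(is.finite(effects)))
  feats <- mpc_features()
  shift <- stats::setNames(rep(0, length(feats)), feats)
  shift[names(effects)] <- effects
  n <- n_path + n_benign
  label <- rep(c(1L, 0L), c(n_path, n_benign))
  withr::with_seed(seed, {
    x <- vapply(feats, function(f) {
      stats::rnorm(n, mean = label * shift[[f]]) }, numeric(n))
  })
  colnames(x) <- feats
  dplyr::bind_cols(
    tibble::tibble(variant_id = sprintf("v%06d", seq_len(n)), label = label),
    tibble::as_tibble(x)
  )
}

#' Simulate case and control cohort variant sets
#'
#' Per-individual, per-bin variant counts are Poisson at the control base
#' rates, multiplied in cases by the per-bin rate multipliers. Each simulated
#' variant is annotated with a `local_oe` drawn uniformly within its bin, so
#' the pair plugs directly into [oe_bin_enrichment()].
#'
#' @param n_case,n_control Cohort sizes (individuals).
#' @param base_rates Expected variants per individual per OE bin (control
#'   rates); bins are the intervals of `breaks`.
#' @param multipliers Case rate multipliers per bin (default all 1).
#' @param breaks OE bin edges (default `seq(0, 1, 0.2)`).
#' @param seed Integer seed.
#' @return A list with `case` and `control`, each a list of `n_individuals`
#'   and `variants` (tibble with `local_oe` and `bin`).
#' @export
simulate_cohorts <- function(n_case, n_control,
                             base_rates = rep(0.02, 5),
                             multipliers = rep(1, length(base_rates)),
                             breaks = seq(0, 1, 0.2), seed = 1) {
  stopifnot(
    length(base_rates) == length(breaks) - 1 ||
      length(base_rates) == length(breaks),
    all(multipliers >= 0), length(multipliers) == length(base_rates)
  )
  nb <- length(base_rates)
  lo <- breaks[seq_len(nb)]
  hi <- if (length(breaks) > nb) breaks[seq_len(nb) + 1] else
    c(breaks[-1], breaks[nb] + diff(breaks)[1])
  draw <- function(n_ind, rates, seed_offset) {
    withr::with_seed(seed + seed_offset, {
      counts <- stats::rpois(nb, n_ind * rates)
      oe <- unlist(lapply(seq_len(nb), function(b) {
        stats::runif(counts[b], lo[b], hi[b])
      }))
    })
    list(
      n_individuals = n_ind,
      variants = tibble::tibble(
        local_oe = oe,
        bin = rep(seq_len(nb), counts)
      )
    )
  }
  list(
    case = draw(n_case, base_rates * multipliers, 0L),
    control = draw(n_control, base_rates, 1L)
  )
}
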