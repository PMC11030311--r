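#' Finalize observed flags on a possible-site table
#'
#' A possible missense site counts as observed when all four criteria hold:
#' allele count > 0, allele frequency below the rare cutoff, variant QC pass,
#' and median coverage > 0. All rows are retained — the universe of possible
#' sites is unchanged; only the `observed` flag is (re)computed.
#'
#' @param sites Site table with columns `allele_count`, `allele_freq`,
#'   `qc_pass`, `coverage`.
#' @param af_cutoff Rare allele-frequency cutoff (default 0.001).
#' @return The input as a tibble with a finalized logical `observed` column.
#' @export
filter_observed <- function(sites, af_cutoff = 0.001) {
  check_columns(sites, c("allele_count", "allele_freq", "qc_pass", "coverage"),
                "sites")
  sites %>%
    dplyr::mutate(
      observed = .data$allele_count > 0 &
        .data$allele_freq < af_cutoff &
        .data$qc_pass &
        .data$coverage > 0
    ) %>%
    tibble::as_tibble()
}

#' Build a per-transcript constraint model
#'
#' Collapses a transcript's possible missense sites to coding-position
#' resolution (summing observed counts and expectations over alternate alleles
#' at the same position — a breakpoint is a coding-position boundary, not an
#' individual substitution) and attaches cumulative observed/expected arrays
#' for O(1) section sums during the breakpoint scan.
#'
#' @param sites Sites of a single transcript, with columns `transcript_id`,
#'   `cds_pos`, `observed`, `mu_adj`.
#' @return An object of class `transcript_model`: a list with
#'   `transcript_id`, `positions` (sorted unique cds positions), `obs`, `exp`
#'   (per-position), `cum_obs`, `cum_exp`, `total_obs`, `total_exp`,
#'   `n_possible` (number of possible substitutions).
#' @export
transcript_model <- function(sites) {
  check_columns(sites, c("transcript_id", "cds_pos", "observed", "mu_adj"),
                "sites")
  tid <- unique(sites$transcript_id)
  if (length(tid) != 1) {
    stop("`transcript_model()` expects sites of a single transcript",
         call. = FALSE)
  }
  per_pos <- sites %>%
    dplyr::group_by(.data$cds_pos) %>%
    dplyr::summarise(
      obs = sum(.data$observed),
      exp = sum(.data$mu_adj),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$cds_pos)
  structure(
    list(
      transcript_id = tid,
      positions = per_pos$cds_pos,
      obs = per_pos$obs,
      exp = per_pos$exp,
      cum_obs = cumsum(per_pos$obs),
      cum_exp = cumsum(per_pos$exp),
      total_obs = sum(per_pos$obs),
      total_exp = sum(per_pos$exp),
      n_possible = nrow(sites)
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "Transcript %s: %d positions, obs %d / exp %.2f (OE %.3f)\n",
    x$transcript_id, length(x$positions), x$total_obs, x$total_exp,
    oe_ratio(x$total_obs, x$total_exp)
  ))
  invisible(x)
}

#' Per-transcript observed/expected summary
#'
#' @param sites Site table for one or more transcripts (columns
#'   `transcript_id`, `cds_pos`, `observed`, `mu_adj`).
#' @return A tibble with one row per transcript: `transcript_id`, `total_obs`,
#'   `total_exp`, `oe`, `n_possible`.
#' @export
transcript_summary <- function(sites) {
  check_columns(sites, c("transcript_id", "observed", "mu_adj"), "sites")
  sites %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(
      total_obs = sum(.data$observed),
      total_exp = sum(.data$mu_adj),
      n_possible = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(oe = oe_ratio(.data$total_obs, .data$total_exp)) %>%
    dplyr::select("transcript_id", "total_obs", "total_exp", "oe",
                  "n_possible")
}

#' Exclude transcripts with outlier variant counts under neutrality
#'
#' Transcripts whose observed counts deviate too strongly from the neutral
#' expectation are unreliable for constraint estimation (annotation or QC
#' artifacts). A transcript is excluded when any functional class has zero
#' expected variants, when any class has too many observed variants
#' (Poisson z-score above `z_bound`), or when synonymous variants — the
#' neutral yardstick — are too few (z below `-z_bound`).
#'
#' @param transcripts Data frame with one row per transcript and columns
#'   `transcript_id`, `obs_syn`, `exp_syn`, `obs_mis`, `exp_mis`, `obs_lof`,
#'   `exp_lof`.
#' @param z_bound Poisson z-score bound (default 4).
#' @return A list with `retained` (tibble, rows passing all checks) and
#'   `excluded` (tibble with a `reason` column, one row per excluded
#'   transcript).
#' @export
filter_outlier_transcripts <- function(transcripts, z_bound = 4) {
  check_columns(transcripts,
                c("transcript_id", "obs_syn", "exp_syn", "obs_mis", "exp_mis",
                  "obs_lof", "exp_lof"),
                "transcripts")
  z <- function(obs, exp) (obs - exp) / sqrt(pmax(exp, 1e-9))
  ann <- transcripts %>%
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$exp_syn <= 0 | .data$exp_mis <= 0 | .data$exp_lof <= 0 ~
          "zero expected",
        z(.data$obs_syn, .data$exp_syn) > z_bound ~ "too many synonymous",
        z(.data$obs_mis, .data$exp_mis) > z_bound ~ "too many missense",
        z(.data$obs_lof, .data$exp_lof) > z_bound ~ "too many pLoF",
        z(.data$obs_syn, .data$exp_syn) < -z_bound ~ "too few synonymous",
        TRUE ~ NA_character_
      )
    )
  list(
    retained = ann %>% dplyr::filter(is.na(.data$reason)) %>%
      dplyr::select(-"reason") %>% tibble::as_tibble(),
    excluded = ann %>% dplyr::filter(!is.na(.data$reason)) %>%
      tibble::as_tibble()
  )
}
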