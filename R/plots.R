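#' Plot the constraint regions of a transcript
#'
#' Step plot of regional missense OE along the coding sequence, one panel per
#' transcript: constrained regions sit below the neutral line at OE = 1.
#'
#' @param regions A region tibble from [search_regions()].
#' @return A ggplot object.
#' @export
plot_regions <- function(regions) {
  ggplot2::ggplot(regions) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$cds_start, xend = .data$cds_end,
                   y = .data$oe, yend = .data$oe, colour = .data$oe),
      linewidth = 2
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_gradient(low = "#b2182b", high = "#2166ac",
                                   limits = c(0, 1), name = "OE") +
    ggplot2::facet_wrap(ggplot2::vars(.data$transcript_id),
                        scales = "free_x") +
    ggplot2::labs(x = "CDS position", y = "Missense OE") +
    ggplot2::ylim(0, 1.05) +
    ggplot2::theme_minimal()
}

#' @param object A `posterior_curve`.
#' @param ... Unused.
#' @rdname local_posterior
#' @method autoplot posterior_curve
#' @export
autoplot.posterior_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$posterior)) +
    ggplot2::labs(x = "Score", y = "Local posterior P(pathogenic)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-bin case/control rate ratios
#'
#' @param enrichment Output of [oe_bin_enrichment()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  df <- dplyr::mutate(
    enrichment,
    bin_label = ifelse(is.finite(.data$oe_hi),
                       sprintf("[%.1f, %.1f)", .data$oe_lo, .data$oe_hi),
                       sprintf("≥ %.1f", .data$oe_lo))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_label, y = .data$rr)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper)
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Local OE bin", y = "Case/control rate ratio") +
    ggplot2::theme_minimal()
}
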