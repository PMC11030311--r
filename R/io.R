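#' Read / write the tab-separated tables the toolkit exchanges
#'
#' All TSVs are plain tab-separated files with a header row; coordinates in
#' TSVs are 1-based inclusive. `read_sites_tsv` checks the site-table schema;
#' the writers format floating point at full precision so files round-trip.
#'
#' @param path File path.
#' @return A tibble.
#' @name rmcr_io
NULL

site_tsv_cols <- c("transcript_id", "cds_pos", "ref", "alt", "context",
                   "methyl_level", "coverage", "allele_count", "allele_freq",
                   "qc_pass")

# ref/alt/context columns hold bases: "T" must never be parsed as logical
seq_cols <- c("transcript_id", "ref", "alt", "context", "chrom")

seq_col_types <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  spec <- lapply(intersect(seq_cols, header),
                 function(x) readr::col_character())
  names(spec) <- intersect(seq_cols, header)
  do.call(readr::cols, c(spec, .default = list(readr::col_guess())))
}

#' @rdname rmcr_io
#' @export
read_sites_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                        col_types = seq_col_types(path))
  check_columns(df, site_tsv_cols, basename(path))
  df
}

#' @rdname rmcr_io
#' @export
read_rates_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                        col_types = seq_col_types(path))
  check_columns(df, c("context", "alt", "methyl_level", "mu"), basename(path))
  df
}

#' @param x A data frame to write.
#' @rdname rmcr_io
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write regions as a TSV summary
#'
#' One row per region: `transcript_id cds_start cds_end obs exp oe chi_sq
#' n_regions_in_transcript`. Coordinates 1-based inclusive.
#'
#' @param regions A region tibble from [search_regions()].
#' @param path Output path.
#' @export
write_regions_tsv <- function(regions, path) {
  cols <- c("transcript_id", "cds_start", "cds_end", "obs", "exp", "oe",
            "chi_sq", "n_regions_in_transcript")
  write_tsv_table(dplyr::select(regions, dplyr::all_of(cols)), path)
}

#' Write regions as BED intervals
#'
#' Maps each region's coding interval to genomic coordinates via the site
#' table and emits 0-based half-open BED rows, one per contiguous genomic
#' piece (regions spanning splice junctions yield one row per exon piece).
#' Name is `transcript_id:region_index`; score is `round(1000 * (1 - oe))`,
#' so more constrained regions score higher.
#'
#' @param regions A region tibble from [search_regions()].
#' @param sites The site table used for the search, with columns `chrom` and
#'   `genomic_pos` in addition to `transcript_id`, `cds_pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, sites, path) {
  check_columns(sites, c("transcript_id", "cds_pos", "chrom", "genomic_pos"),
                "sites")
  map <- sites %>%
    dplyr::distinct(.data$transcript_id, .data$cds_pos, .data$chrom,
                    .data$genomic_pos)
  rows <- purrr::pmap_dfr(
    dplyr::select(regions, "transcript_id", "region_index", "cds_start",
                  "cds_end", "oe"),
    function(transcript_id, region_index, cds_start, cds_end, oe) {
      seg <- map %>%
        dplyr::filter(.data$transcript_id == !!transcript_id,
                      .data$cds_pos >= cds_start,
                      .data$cds_pos <= cds_end) %>%
        dplyr::arrange(.data$genomic_pos)
      if (nrow(seg) == 0) return(NULL)
      # split into runs of consecutive genomic positions (exon pieces)
      seg$run <- cumsum(c(1, diff(seg$genomic_pos) != 1))
      seg %>%
        dplyr::group_by(.data$chrom, .data$run) %>%
        dplyr::summarise(start = min(.data$genomic_pos) - 1L,
                         end = max(.data$genomic_pos),
                         .groups = "drop") %>%
        dplyr::transmute(
          .data$chrom, .data$start, .data$end,
          name = paste0(transcript_id, ":", region_index),
          score = round(1000 * (1 - oe)),
          strand = "."
        )
    }
  )
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_regions_bed()]
#'
#' @param path BED path.
#' @return A tibble with `chrom`, `start` (0-based), `end`, `name`, `score`,
#'   `strand`.
#' @export
read_regions_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "name", "score",
                                "strand"),
                  show_col_types = FALSE)
}
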