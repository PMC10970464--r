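#' Region-filter configuration
#'
#' @param max_ssr_len maximum SSR length in bp (default 80); longer runs are
#'   excluded as `too_long`.
#' @param min_separation minimum bp of sequence required between neighbouring
#'   SSRs and between an SSR and the contig end (default 200); this is also
#'   the flanking window handed to primer design.
#' @return a list of class `region_config`.
#' @export
region_config <- function(max_ssr_len = 80L, min_separation = 200L) {
  stopifnot(max_ssr_len > 0L, min_separation > 0L)
  structure(list(max_ssr_len = as.integer(max_ssr_len),
                 min_separation = as.integer(min_separation)),
            class = "region_config")
}

#' Classify SSRs into promising regions and exclusions
#'
#' Applies the region filters in fixed precedence order — `composite`
#' (member of a compound group), `too_long`, `near_ssr`, `near_contig_end` —
#' so that every SSR receives exactly one status; survivors are
#' `promising`. Separation is measured gap-wise: bases strictly between two
#' runs, and bases between a run's own endpoints and the contig ends.
#' Distances to neighbours are measured against every other SSR record
#' regardless of that neighbour's own status (a simple SSR close to a
#' compound group is `near_ssr`).
#'
#' @param ssrs tibble from [group_compounds()].
#' @param assembly the `ssr_assembly` the SSRs were mined from.
#' @param cfg a [region_config()].
#' @return tibble: the input columns plus `status`, `flank_up`, `flank_down`
#'   (bp of sequence available before hitting the nearest neighbour or the
#'   contig end).
#' @seealso [region_summary()]
#' @export
analyze_regions <- function(ssrs, assembly, cfg = region_config()) {
  lens <- contig_lengths(assembly)
  if (nrow(ssrs) == 0L) {
    return(dplyr::mutate(ssrs, status = character(),
                         flank_up = integer(), flank_down = integer()))
  }
  if (!all(ssrs$contig %in% lens$contig)) {
    abort("ssrs reference contigs absent from the assembly")
  }
  out <- ssrs |>
    dplyr::left_join(lens, by = "contig", suffix = c("", ".contig")) |>
    dplyr::rename(contig_len = "length.contig")
  if (any(out$start < 1L | out$end > out$contig_len)) {
    abort("SSR interval outside contig bounds")
  }
  out <- out |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      gap_prev = .data$start - dplyr::lag(.data$end) - 1L,
      gap_next = dplyr::lead(.data$start) - .data$end - 1L,
      flank_up = pmin(.data$start - 1L, .data$gap_prev, na.rm = TRUE),
      flank_down = pmin(.data$contig_len - .data$end, .data$gap_next, na.rm = TRUE)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      near_other = pmin(.data$gap_prev, .data$gap_next, na.rm = TRUE) <
        cfg$min_separation,
      near_other = !is.na(.data$near_other) & .data$near_other,
      status = dplyr::case_when(
        !is.na(.data$compound_group) ~ "composite",
        .data$length > cfg$max_ssr_len ~ "too_long",
        .data$near_other ~ "near_ssr",
        .data$start - 1L < cfg$min_separation |
          .data$contig_len - .data$end < cfg$min_separation ~ "near_contig_end",
        TRUE ~ "promising"
      )
    ) |>
    dplyr::select(-"gap_prev", -"gap_next", -"near_other", -"contig_len")
  out
}

#' Step-count summary of a region analysis
#'
#' Counts mirror the pipeline bookkeeping table: the total and the
#' `composite` row count each compound group once; the identity
#' `total == promising + composite + too_long + near_ssr + near_contig_end`
#' holds on every input.
#'
#' @param verdicts tibble from [analyze_regions()].
#' @return one-row tibble with columns `total`, `composite`, `too_long`,
#'   `near_ssr`, `near_contig_end`, `promising`.
#' @export
region_summary <- function(verdicts) {
  n_groups <- dplyr::n_distinct(verdicts$compound_group, na.rm = TRUE)
  n_simple <- sum(is.na(verdicts$compound_group))
  st <- verdicts$status[is.na(verdicts$compound_group)]
  tibble(
    total = n_simple + n_groups,
    composite = n_groups,
    too_long = sum(st == "too_long"),
    near_ssr = sum(st == "near_ssr"),
    near_contig_end = sum(st == "near_contig_end"),
    promising = sum(st == "promising")
  )
}

#' Write the region table
#'
#' Tab-separated, 1-based inclusive coordinates.
#'
#' @param verdicts tibble from [analyze_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(verdicts, path) {
  readr::write_tsv(verdicts, path)
  invisible(path)
}
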