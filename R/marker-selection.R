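#' Longest run of the designed motif inside an amplicon
#'
#' Scans the amplicon (oriented forward-primer first) for perfect
#' complete-unit runs whose motif is a cyclic rotation of the designed
#' motif — orientation is fixed by the primer pair, so the reverse
#' complement is deliberately not considered — and returns the longest such
#' run with at least `min_units` units.
#'
#' @param seq amplicon sequence, forward-primer-first orientation.
#' @param motif the designed (primitive) motif.
#' @param min_units minimum complete units for verification (default 5,
#'   deliberately below the mining threshold so that a shorter allele in
#'   another assembly still verifies).
#' @return integer run length in bp, or `NA` if no qualifying run exists.
#' @export
scan_amplicon_ssr <- function(seq, motif, min_units = 5L) {
  u <- nchar(motif)
  runs <- tandem_runs(seq, u)
  runs <- runs[runs$repeats >= min_units &
                 runs$motif %in% motif_rotations(motif), , drop = FALSE]
  if (nrow(runs) == 0L) return(NA_integer_)
  max(runs$end - runs$start + 1L)
}

#' Evaluate markers against their cross-assembly amplification evidence
#'
#' Assigns each marker the first failing criterion, in fixed order:
#' `absent` (no amplicon in some assembly), `multi_site` (more than one
#' amplicon in some assembly), `motif_mismatch` (an amplicon lacks a run of
#' the designed motif), `flank_variation` (amplicon length minus SSR run
#' length differs between assemblies, i.e. the length difference is not
#' purely repeat-number), `monomorphic` (no repeat-length polymorphism),
#' else `selected`.
#'
#' @param markers tibble from [design_markers()].
#' @param amplicons tibble from [amplify_markers()].
#' @param assembly_labels character vector of all assembly labels the
#'   markers were amplified in (order preserved in reports).
#' @param polymorphism_mode `"any_differ"` (default: SSR run lengths must
#'   not all be equal) or `"all_distinct"` (all pairwise different).
#' @param min_units passed to [scan_amplicon_ssr()].
#' @return tibble: `marker_id`, `verdict`, `detail`, plus the per-assembly
#'   evidence nested in [marker_amplicon_table()] form via the `amplicons`
#'   input.
#' @export
evaluate_markers <- function(markers, amplicons, assembly_labels,
                             polymorphism_mode = c("any_differ", "all_distinct"),
                             min_units = 5L) {
  polymorphism_mode <- match.arg(polymorphism_mode)
  if (nrow(markers) == 0L) {
    return(tibble(marker_id = character(), verdict = character(),
                  detail = character()))
  }
  purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    m <- markers[i, ]
    amps <- amplicons[amplicons$marker_id == m$marker_id, , drop = FALSE]
    counts <- table(factor(amps$assembly, levels = assembly_labels))
    verdict <- NULL; detail <- ""
    if (any(counts == 0L)) {
      verdict <- "absent"
      detail <- paste("no amplicon in",
                      paste(assembly_labels[counts == 0L], collapse = ","))
    } else if (any(counts > 1L)) {
      verdict <- "multi_site"
      detail <- paste0(paste(assembly_labels[counts > 1L], collapse = ","),
                       ": ", paste(counts[counts > 1L], collapse = ","),
                       " amplicons")
    } else {
      amps <- amps[match(assembly_labels, amps$assembly), , drop = FALSE]
      run_len <- vapply(amps$seq, scan_amplicon_ssr, integer(1),
                        motif = m$motif, min_units = min_units,
                        USE.NAMES = FALSE)
      if (anyNA(run_len)) {
        verdict <- "motif_mismatch"
        detail <- paste("designed motif not found in",
                        paste(assembly_labels[is.na(run_len)], collapse = ","))
      } else {
        flanks <- amps$length - run_len
        runs_txt <- paste0(assembly_labels, ":", amps$length, "/", run_len,
                           collapse = " ")
        if (dplyr::n_distinct(flanks) > 1L) {
          verdict <- "flank_variation"
          detail <- runs_txt
        } else {
          mono <- switch(polymorphism_mode,
                         any_differ = dplyr::n_distinct(run_len) == 1L,
                         all_distinct = anyDuplicated(run_len) > 0L)
          verdict <- if (mono) "monomorphic" else "selected"
          detail <- runs_txt
        }
      }
    }
    tibble(marker_id = m$marker_id, verdict = verdict, detail = detail)
  })
}

#' Per-assembly amplicon evidence table for selected markers
#'
#' One row per marker and assembly with 1-based coordinates, amplicon
#' length, SSR run length and the inferred repeat number.
#'
#' @param markers tibble from [design_markers()].
#' @param amplicons tibble from [amplify_markers()].
#' @param evaluations tibble from [evaluate_markers()].
#' @param min_units passed to [scan_amplicon_ssr()].
#' @return long tibble: `marker_id`, `assembly`, `contig`, `start`, `end`,
#'   `amplicon_len`, `ssr_run_len`, `repeats_inferred`.
#' @export
marker_amplicon_table <- function(markers, amplicons, evaluations,
                                  min_units = 5L) {
  sel <- evaluations$marker_id[evaluations$verdict == "selected"]
  rows <- amplicons[amplicons$marker_id %in% sel, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(tibble(marker_id = character(), assembly = character(),
                  contig = character(), start = integer(), end = integer(),
                  amplicon_len = integer(), ssr_run_len = integer(),
                  repeats_inferred = numeric()))
  }
  rows |>
    dplyr::left_join(markers[, c("marker_id", "motif", "unit_len")],
                     by = "marker_id") |>
    dplyr::mutate(
      ssr_run_len = purrr::map2_int(.data$seq, .data$motif,
                                    ~ scan_amplicon_ssr(.x, .y, min_units)),
      repeats_inferred = .data$ssr_run_len / .data$unit_len,
      amplicon_len = .data$length
    ) |>
    dplyr::select("marker_id", "assembly", "contig", "start", "end",
                  "amplicon_len", "ssr_run_len", "repeats_inferred")
}

#' Write the final marker report
#'
#' Writes the final table (one row per selected marker, with primer
#' properties and per-assembly contig/coordinates/lengths spread into
#' columns), the full audit table of all verdicts, and returns the final
#' table invisibly.
#'
#' @param evaluations tibble from [evaluate_markers()].
#' @param markers tibble from [design_markers()].
#' @param amplicons tibble from [amplify_markers()].
#' @param dir output directory (created if needed).
#' @param min_units passed to [scan_amplicon_ssr()].
#' @return the wide final table, invisibly.
#' @export
write_final_report <- function(evaluations, markers, amplicons, dir,
                               min_units = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_asm <- marker_amplicon_table(markers, amplicons, evaluations, min_units)
  base_cols <- markers[, c("marker_id", "motif", "fwd", "rev",
                           "tm_f", "tm_r", "gc_f", "gc_r")]
  base_cols$motif_canonical <- normalize_motif(base_cols$motif)
  sel <- evaluations$marker_id[evaluations$verdict == "selected"]
  final <- base_cols[base_cols$marker_id %in% sel, , drop = FALSE]
  if (nrow(per_asm) > 0L) {
    wide <- per_asm |>
      tidyr::pivot_wider(
        id_cols = "marker_id",
        names_from = "assembly",
        values_from = c("contig", "start", "end", "amplicon_len",
                        "ssr_run_len", "repeats_inferred"),
        names_glue = "{assembly}_{.value}"
      )
    final <- dplyr::left_join(final, wide, by = "marker_id")
  }
  readr::write_tsv(final, file.path(dir, "final_markers.tsv"))
  audit <- dplyr::left_join(evaluations,
                            markers[, c("marker_id", "contig", "ssr_start",
                                        "ssr_end", "motif")],
                            by = "marker_id")
  readr::write_tsv(audit, file.path(dir, "marker_audit.tsv"))
  invisible(final)
}
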