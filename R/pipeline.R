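#' Pipeline configuration
#'
#' Bundles every stage's settings with the field-standard defaults: mining
#' thresholds 10 (di) / 7 (tri) repeats, compound gap 100 bp, max SSR 80 bp,
#' 200 bp separation, product 100-250 bp, primers 19-23 bp at 58-62 deg C
#' and 40-60 % GC, 5 bp low-complexity allowance, 1500 bp amplification
#' limit.
#'
#' @param thresholds an [ssr_thresholds()] map.
#' @param compound_gap maximum gap for compound grouping, bp.
#' @param region a [region_config()].
#' @param design a [design_config()].
#' @param allowance an [allowance_config()].
#' @param max_amplicon maximum in silico product span, bp.
#' @param polymorphism_mode `"any_differ"` or `"all_distinct"`; with two
#'   assemblies the modes coincide.
#' @param min_units minimum repeat units for amplicon motif verification.
#' @param masks optional mask-interval tibble (see [read_mask_bed()]),
#'   applied to the mining assembly's products.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = ssr_thresholds(),
                            compound_gap = 100L,
                            region = region_config(),
                            design = design_config(),
                            allowance = allowance_config(),
                            max_amplicon = 1500L,
                            polymorphism_mode = "any_differ",
                            min_units = 5L,
                            masks = NULL) {
  structure(list(thresholds = thresholds, compound_gap = compound_gap,
                 region = region, design = design, allowance = allowance,
                 max_amplicon = max_amplicon,
                 polymorphism_mode = polymorphism_mode,
                 min_units = min_units, masks = masks),
            class = "pipeline_config")
}

# content hash of arbitrary R objects, via a serialized temp file
content_hash <- function(...) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(...), tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the six-step marker pipeline
#'
#' Executes, in order: (1) SSR mining and compound grouping on the first
#' assembly, (2) region analysis, (3) primer design, (4) the low-complexity
#' / mask screen, (5) in silico PCR in every assembly, (6) marker
#' evaluation and the final report. Steps 1-4 use only the first assembly;
#' a marker must then amplify exactly once in each assembly and vary only
#' in SSR run length to be selected.
#'
#' Output is bit-identical for any `threads` value (parallelism is
#' per-record with a deterministic merge and no step uses random numbers).
#' When `out_dir` is populated from a previous run on identical inputs
#' (checked by content checksum) the cached result is reused.
#'
#' @param assemblies list (length >= 2) of FASTA paths or `ssr_assembly`
#'   objects; the first is the mining assembly.
#' @param out_dir optional output directory for per-step artifact tables,
#'   the final report and the summary block.
#' @param config a [pipeline_config()].
#' @param threads worker count for the per-record stages.
#' @param resume reuse `out_dir` artifacts when inputs are unchanged.
#' @return an object of class `ssr_pipeline`; see [tidy.ssr_pipeline()],
#'   [glance.ssr_pipeline()], [autoplot.ssr_pipeline()].
#' @export
run_pipeline <- function(assemblies, out_dir = NULL,
                         config = pipeline_config(), threads = 1L,
                         resume = TRUE) {
  assemblies <- as_assembly_list(assemblies)
  if (length(assemblies) < 2L) abort("need at least 2 assemblies")
  labels <- vapply(assemblies, `[[`, character(1), "label")
  hash <- content_hash(lapply(assemblies, `[[`, "seq"), labels,
                       config[setdiff(names(config), "masks")],
                       config$masks)
  cache <- if (!is.null(out_dir)) file.path(out_dir, "result.rds") else NULL
  manifest <- if (!is.null(out_dir)) file.path(out_dir, "manifest.txt") else NULL
  if (resume && !is.null(cache) && file.exists(cache) &&
      file.exists(manifest) && identical(readLines(manifest)[1], hash)) {
    return(readRDS(cache))
  }

  asm_a <- assemblies[[1L]]
  # step 1: mining
  ssrs <- find_ssrs(asm_a, config$thresholds, threads = threads) |>
    group_compounds(config$compound_gap)
  # step 2: region analysis
  regions <- analyze_regions(ssrs, asm_a, config$region)
  rsum <- region_summary(regions)
  promising <- regions[regions$status == "promising", , drop = FALSE]
  # step 3: primer design
  markers <- design_markers(promising, asm_a, config$design,
                            flank = config$region$min_separation,
                            threads = threads)
  # the pipeline carries one (the best-ranked) pair per region
  markers <- markers |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$contig, names(asm_a$seq)), .data$ssr_start)
  n_without <- nrow(promising) - nrow(markers)
  # step 4: low-complexity / mask screen
  complexity <- check_markers(markers, asm_a, config$allowance, config$masks)
  pass_ids <- complexity$marker_id[complexity$status == "pass"]
  tested <- markers[markers$marker_id %in% pass_ids, , drop = FALSE]
  # step 5: in silico PCR in all assemblies
  amplicons <- amplify_markers(tested, assemblies, config$max_amplicon,
                               threads = threads)
  # step 6: evaluation
  evaluations <- evaluate_markers(tested, amplicons, labels,
                                  config$polymorphism_mode,
                                  config$min_units)
  once <- amplicons |>
    dplyr::count(.data$marker_id, .data$assembly) |>
    tidyr::pivot_wider(names_from = "assembly", values_from = "n",
                       values_fill = 0L)
  cum_once <- vapply(seq_along(labels), function(k) {
    if (nrow(once) == 0L) return(0L)
    cols <- labels[seq_len(k)]
    present <- cols[cols %in% names(once)]
    if (length(present) < k) return(0L)
    sum(rowSums(as.matrix(once[, present, drop = FALSE]) == 1L) == k)
  }, integer(1))

  summary_tbl <- dplyr::bind_rows(
    tibble(step = 1L, description = "Total no. of SSRs found",
           included = rsum$total, excluded = NA_integer_),
    tibble(step = 2L,
           description = c("No. of composite SSRs", "No. of long SSRs",
                           "No. of SSRs close to another SSR",
                           "No. of SSRs close to the contig end",
                           "No. of promising SSR regions"),
           included = c(NA, NA, NA, NA, rsum$promising),
           excluded = c(rsum$composite, rsum$too_long, rsum$near_ssr,
                        rsum$near_contig_end, NA)),
    tibble(step = 3L,
           description = c("No. of SSR regions without suitable primers",
                           "No. of SSR regions with suitable primers"),
           included = c(NA, nrow(markers)),
           excluded = c(n_without, NA)),
    tibble(step = 4L,
           description = c("No. of regions with low complexity",
                           "No. of regions close to a coding region",
                           "No. of promising SSR markers"),
           included = c(NA, NA, nrow(tested)),
           excluded = c(sum(complexity$status == "extra_low_complexity"),
                        sum(complexity$status == "masked_overlap"), NA)),
    tibble(step = 5L,
           description = paste("No. of markers amplified once in", labels),
           included = cum_once, excluded = NA_integer_),
    tibble(step = 6L, description = "Final no. of SSR markers",
           included = sum(evaluations$verdict == "selected"),
           excluded = NA_integer_)
  )

  res <- structure(list(
    labels = labels, config = config, hash = hash,
    ssrs = ssrs, regions = regions, region_summary = rsum,
    markers = markers, n_without_primers = n_without,
    complexity = complexity, amplicons = amplicons,
    evaluations = evaluations, summary = summary_tbl
  ), class = "ssr_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_misa_table(ssrs, file.path(out_dir, "step1_ssrs.tsv"))
    write_region_table(regions, file.path(out_dir, "step2_regions.tsv"))
    readr::write_tsv(markers, file.path(out_dir, "step3_markers.tsv"))
    readr::write_tsv(complexity, file.path(out_dir, "step4_complexity.tsv"))
    readr::write_tsv(dplyr::select(amplicons, -"seq"),
                     file.path(out_dir, "step5_amplicons.tsv"))
    write_final_report(evaluations, tested, amplicons, out_dir,
                       config$min_units)
    writeLines(format_summary(summary_tbl), file.path(out_dir, "summary.txt"))
    writeLines(hash, manifest)
    saveRDS(res, cache, version = 2)
  }
  res
}

# plain-text step summary block (step table layout)
format_summary <- function(s) {
  c("Steps\tDescription\tIncluded\tExcluded",
    vapply(seq_len(nrow(s)), function(i) {
      paste(paste0("(", s$step[i], ")"), s$description[i],
            ifelse(is.na(s$included[i]), "", s$included[i]),
            ifelse(is.na(s$excluded[i]), "", s$excluded[i]),
            sep = "\t")
    }, character(1)))
}

#' @export
print.ssr_pipeline <- function(x, ...) {
  cat("<ssr_pipeline> ", length(x$labels), " assemblies (",
      paste(x$labels, collapse = ", "), ")\n", sep = "")
  cat(paste(format_summary(x$summary), collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy the pipeline result into the marker audit table
#'
#' @param x an `ssr_pipeline`.
#' @param ... unused.
#' @return tibble: one row per tested marker with verdict and detail.
#' @method tidy ssr_pipeline
#' @export
tidy.ssr_pipeline <- function(x, ...) {
  dplyr::left_join(x$evaluations,
                   x$markers[, c("marker_id", "contig", "ssr_start",
                                 "ssr_end", "motif", "unit_len")],
                   by = "marker_id")
}

#' One-row pipeline summary
#'
#' @param x an `ssr_pipeline`.
#' @param ... unused.
#' @return one-row tibble of step counts.
#' @method glance ssr_pipeline
#' @export
glance.ssr_pipeline <- function(x, ...) {
  rs <- x$region_summary
  tibble(
    n_assemblies = length(x$labels),
    ssrs_total = rs$total,
    composite = rs$composite, too_long = rs$too_long,
    near_ssr = rs$near_ssr, near_contig_end = rs$near_contig_end,
    promising_regions = rs$promising,
    with_primers = nrow(x$markers),
    without_primers = x$n_without_primers,
    low_complexity = sum(x$complexity$status == "extra_low_complexity"),
    masked = sum(x$complexity$status == "masked_overlap"),
    markers_tested = sum(x$complexity$status == "pass"),
    selected = sum(x$evaluations$verdict == "selected")
  )
}

#' Funnel plot of pipeline step counts
#'
#' @param object an `ssr_pipeline`.
#' @param ... unused.
#' @return a ggplot showing how many candidates survive each step.
#' @method autoplot ssr_pipeline
#' @export
autoplot.ssr_pipeline <- function(object, ...) {
  g <- glance.ssr_pipeline(object)
  df <- tibble(
    step = factor(c("SSRs", "promising regions", "with primers",
                    "passed complexity", "selected"),
                  levels = c("SSRs", "promising regions", "with primers",
                             "passed complexity", "selected")),
    n = c(g$ssrs_total, g$promising_regions, g$with_primers,
          g$markers_tested, g$selected)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "candidates remaining",
                  title = "Marker pipeline funnel") +
    ggplot2::theme_minimal()
}

#' Amplicon lengths of selected markers across assemblies
#'
#' @param x an `ssr_pipeline`.
#' @return a ggplot: per selected marker, amplicon length by assembly —
#'   visualising the repeat-length polymorphism the pipeline selects for.
#' @export
plot_marker_lengths <- function(x) {
  sel <- x$evaluations$marker_id[x$evaluations$verdict == "selected"]
  df <- x$amplicons[x$amplicons$marker_id %in% sel, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker_id, y = .data$length,
                                   colour = .data$assembly)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "amplicon length (bp)",
                  colour = "assembly") +
    ggplot2::theme_minimal()
}
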