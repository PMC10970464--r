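#' Low-complexity allowance configuration
#'
#' A marker's inter-primer segment is expected to contain one
#' low-complexity stretch: the target SSR itself, possibly extended by a few
#' bases because a relaxed detector sees partial trailing units that strict
#' complete-unit mining does not (for `ATGATGAT` mining reports the 6 bp
#' `ATGATG` while the detector flags all 8 bp). `overhang` sets how many
#' such surrounding bases are tolerated.
#'
#' @param overhang bp a flagged stretch may extend beyond the SSR on either
#'   side (default 5).
#' @param lc_min_len minimum stretch length in bp to flag (default 12).
#' @param lc_max_unit largest repeat unit scanned, 1-6 (default 6).
#' @return a list of class `allowance_config`.
#' @export
allowance_config <- function(overhang = 5L, lc_min_len = 12L,
                             lc_max_unit = 6L) {
  stopifnot(overhang >= 0L, lc_min_len >= 2L,
            lc_max_unit >= 1L, lc_max_unit <= 6L)
  structure(list(overhang = as.integer(overhang),
                 lc_min_len = as.integer(lc_min_len),
                 lc_max_unit = as.integer(lc_max_unit)),
            class = "allowance_config")
}

#' Find low-complexity stretches in a segment
#'
#' Flags maximal perfect tandem stretches (partial trailing units included)
#' of any primitive unit of length `1..lc_max_unit` whose total span is at
#' least `lc_min_len` bp; overlapping or adjacent stretches are merged.
#'
#' @param segment nucleotide string (the product sequence between, and
#'   excluding, the primers).
#' @param cfg an [allowance_config()].
#' @return tibble of flagged intervals (`start`, `end`, 1-based inclusive,
#'   segment coordinates), sorted and disjoint.
#' @export
find_low_complexity <- function(segment, cfg = allowance_config()) {
  runs <- tandem_runs(segment, seq_len(cfg$lc_max_unit))
  runs <- runs[runs$stretch_end - runs$stretch_start + 1L >= cfg$lc_min_len, ,
               drop = FALSE]
  merge_intervals(tibble(start = runs$stretch_start, end = runs$stretch_end))
}

#' Screen designed markers for extra low-complexity sequence and masks
#'
#' A marker passes when every flagged stretch of its inter-primer segment
#' lies within the SSR extended by `overhang` bp on each side, and its
#' product overlaps no mask interval. Failure statuses, in precedence
#' order: `extra_low_complexity`, then `masked_overlap`. When `masks` is
#' `NULL` the mask check is skipped with a message (the pipeline carries no
#' annotation of its own; masks are the proxy for coding-region proximity).
#'
#' @param markers tibble from [design_markers()].
#' @param assembly the `ssr_assembly` the markers were designed on.
#' @param cfg an [allowance_config()].
#' @param masks optional tibble of mask intervals (`contig`, `start`, `end`,
#'   1-based inclusive) from [read_mask_bed()] or [read_mask_rmout()].
#' @return tibble: `marker_id`, `status` (`pass`, `extra_low_complexity` or
#'   `masked_overlap`), `flagged` (flagged intervals in segment coordinates,
#'   `"start-end"` joined by `;`, empty string if none).
#' @export
check_markers <- function(markers, assembly, cfg = allowance_config(),
                          masks = NULL) {
  if (is.null(masks)) {
    message("no mask intervals supplied; coding-proximity check skipped")
  } else if (!all(masks$contig %in% names(assembly$seq))) {
    abort("mask intervals reference contigs absent from the assembly")
  }
  out <- purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    m <- markers[i, ]
    seg_start <- m$fwd_end + 1L
    seg_end <- m$rev_start - 1L
    segment <- extract_seq(assembly, m$contig, seg_start, seg_end)
    flagged <- find_low_complexity(segment, cfg)
    lo <- (m$ssr_start - seg_start + 1L) - cfg$overhang
    hi <- (m$ssr_end - seg_start + 1L) + cfg$overhang
    extra <- nrow(flagged) > 0L &&
      any(flagged$start < lo | flagged$end > hi)
    masked <- FALSE
    if (!is.null(masks) && !extra) {
      mm <- masks[masks$contig == m$contig, , drop = FALSE]
      masked <- nrow(mm) > 0L &&
        any(mm$start <= m$product_end & mm$end >= m$product_start)
    }
    tibble(
      marker_id = m$marker_id,
      status = if (extra) "extra_low_complexity"
               else if (masked) "masked_overlap" else "pass",
      flagged = paste(paste0(flagged$start, "-", flagged$end),
                      collapse = ";")
    )
  })
  if (nrow(out) == 0L) {
    out <- tibble(marker_id = character(), status = character(),
                  flagged = character())
  }
  out
}

#' Read mask intervals from a BED file
#'
#' @param path BED file (0-based half-open on disk; converted to 1-based
#'   inclusive).
#' @return tibble with columns `contig`, `start`, `end`.
#' @export
read_mask_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  tibble(contig = as.character(gr$seqnames),
         start = as.integer(gr$start),
         end = as.integer(gr$end))
}

#' Read mask intervals from a RepeatMasker-style .out file
#'
#' Whitespace-delimited with three header lines; query name and 1-based
#' inclusive begin/end are taken from columns 5-7.
#'
#' @param path path to the `.out` file.
#' @return tibble with columns `contig`, `start`, `end`.
#' @export
read_mask_rmout <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  tibble(
    contig = vapply(fields, `[[`, character(1), 5L),
    start = as.integer(vapply(fields, `[[`, character(1), 6L)),
    end = as.integer(vapply(fields, `[[`, character(1), 7L))
  )
}
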