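#' Mining thresholds per motif length
#'
#' Unit lengths absent from the map are not searched. Defaults follow the
#' common mining convention for marker work: at least 10 repeats for
#' dinucleotide and 7 for trinucleotide motifs; mono- and 4-6 bp motifs are
#' supported but off by default.
#'
#' @param ... named minimum repeat counts, names are unit lengths, e.g.
#'   `ssr_thresholds("2" = 10, "3" = 7)`.
#' @return named integer vector of class `ssr_thresholds`.
#' @export
ssr_thresholds <- function(...) {
  x <- c(...)
  if (length(x) == 0L) x <- c("2" = 10L, "3" = 7L)
  u <- as.integer(names(x))
  if (any(is.na(u)) || any(u < 1L) || any(u > 6L)) {
    abort("threshold names must be unit lengths 1-6")
  }
  x <- as.integer(x)
  if (any(x < 2L)) abort("minimum repeat counts must be >= 2")
  names(x) <- u
  structure(x[order(u)], class = "ssr_thresholds")
}

#' Find perfect microsatellite runs in an assembly
#'
#' Scans every contig for maximal runs of complete repeat units whose motif
#' length is listed in `thresholds` and whose repeat count meets that
#' length's minimum. Runs are maximal (not extendable by one full unit on
#' either side), contain complete units only (partial trailing units are
#' excluded), and are reported with the primitive (shortest-unit) motif
#' only. `N` never participates in a run. When two same-unit-length runs
#' would overlap by a few bases (period change mid-stretch), the scan is
#' greedy left-to-right: the later run is trimmed to start after the
#' accepted one and kept only if it still meets its threshold.
#'
#' @param assembly an `ssr_assembly` (or a single named character sequence).
#' @param thresholds an [ssr_thresholds()] map.
#' @param threads contigs are scanned in parallel when > 1; output is
#'   identical for any value.
#' @return tibble with columns `contig`, `start`, `end` (1-based inclusive),
#'   `motif` (as found on the plus strand), `unit_len`, `repeats`, `length`,
#'   and `compound_group` (`NA` until [group_compounds()] is applied),
#'   sorted by contig file order then start.
#' @seealso [group_compounds()], [write_misa_table()]
#' @export
find_ssrs <- function(assembly, thresholds = ssr_thresholds(), threads = 1L) {
  if (!inherits(assembly, "ssr_assembly")) {
    assembly <- new_assembly(assembly, label = "assembly")
  }
  unit_lens <- as.integer(names(thresholds))
  per_contig <- map_threads(seq_along(assembly$seq), function(i) {
    runs <- tandem_runs(assembly$seq[[i]], unit_lens)
    runs <- runs[runs$repeats >= unclass(thresholds)[as.character(runs$unit_len)], , drop = FALSE]
    if (nrow(runs) > 0L) {
      runs <- trim_same_unit_overlaps(runs, assembly$seq[[i]],
                                      unclass(thresholds))
    }
    if (nrow(runs) == 0L) return(NULL)
    tibble(contig = names(assembly$seq)[i],
           start = runs$start, end = runs$end, motif = runs$motif,
           unit_len = runs$unit_len, repeats = runs$repeats,
           length = runs$end - runs$start + 1L)
  }, threads = threads)
  res <- dplyr::bind_rows(per_contig)
  if (nrow(res) == 0L) {
    res <- tibble(contig = character(), start = integer(), end = integer(),
                  motif = character(), unit_len = integer(),
                  repeats = integer(), length = integer())
  }
  res$compound_group <- NA_integer_
  res
}

# Greedy left-to-right resolution of rare same-unit-length overlaps
# (< unit_len bp, where the period changes mid-stretch, e.g. ACACACTCTCTC).
trim_same_unit_overlaps <- function(runs, seq, minima) {
  runs <- dplyr::arrange(runs, .data$start, .data$unit_len)
  last_end <- integer(7)  # per unit length, 0 = none accepted yet
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    u <- runs$unit_len[i]
    if (runs$start[i] <= last_end[u]) {
      ns <- last_end[u] + 1L
      reps <- (runs$stretch_end[i] - ns + 1L) %/% u
      if (reps < minima[[as.character(u)]]) next
      runs$start[i] <- ns
      runs$motif[i] <- substr(seq, ns, ns + u - 1L)
      runs$repeats[i] <- reps
      runs$end[i] <- ns + reps * u - 1L
    }
    keep[i] <- TRUE
    last_end[u] <- runs$end[i]
  }
  dplyr::arrange(runs[keep, , drop = FALSE], .data$start, .data$unit_len)
}

#' Group neighbouring SSRs into compound (composite) loci
#'
#' Consecutive records on the same contig whose gap (bases strictly between
#' the two runs) is at most `max_gap` share a compound group; chains are
#' transitive. Singleton records keep `compound_group = NA`.
#'
#' @param ssrs tibble from [find_ssrs()], sorted by contig then start.
#' @param max_gap maximum gap in bp (default 100, the conventional mining
#'   default for interrupted/composite loci).
#' @return the same tibble with `compound_group` filled in (integer ids,
#'   unique across the table).
#' @export
group_compounds <- function(ssrs, max_gap = 100L) {
  if (nrow(ssrs) == 0L) return(ssrs)
  unsorted <- ssrs |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(bad = is.unsorted(.data$start), .groups = "drop")
  if (any(unsorted$bad)) abort("ssrs must be sorted by start within contig")
  ssrs |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      gap_prev = .data$start - dplyr::lag(.data$end) - 1L,
      new_chain = is.na(.data$gap_prev) | .data$gap_prev > max_gap,
      chain = cumsum(.data$new_chain)
    ) |>
    dplyr::group_by(.data$contig, .data$chain) |>
    dplyr::mutate(chain_size = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      key = ifelse(.data$chain_size >= 2L,
                   paste(.data$contig, .data$chain), NA_character_),
      compound_group = as.integer(factor(.data$key, levels = unique(stats::na.omit(.data$key))))
    ) |>
    dplyr::select(-"gap_prev", -"new_chain", -"chain", -"chain_size", -"key")
}

#' Write a MISA-style SSR table
#'
#' Tab-separated, 1-based inclusive coordinates. Singleton records get type
#' `p<unit_len>`; a compound group is written as one row of type `c`
#' spanning the group, with its members' `(motif)count` notations joined.
#'
#' @param ssrs tibble from [find_ssrs()] / [group_compounds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_misa_table <- function(ssrs, path) {
  simple <- ssrs[is.na(ssrs$compound_group), , drop = FALSE]
  rows <- tibble(
    ID = simple$contig,
    type = paste0("p", simple$unit_len),
    SSR = paste0("(", simple$motif, ")", simple$repeats),
    size = simple$length,
    start = simple$start,
    end = simple$end
  )
  comp <- ssrs[!is.na(ssrs$compound_group), , drop = FALSE]
  if (nrow(comp) > 0L) {
    crows <- comp |>
      dplyr::group_by(.data$compound_group) |>
      dplyr::summarise(
        ID = dplyr::first(.data$contig),
        type = "c",
        SSR = paste0("(", .data$motif, ")", .data$repeats, collapse = "*"),
        size = max(.data$end) - min(.data$start) + 1L,
        start = min(.data$start),
        end = max(.data$end),
        .groups = "drop"
      ) |>
      dplyr::select(-"compound_group")
    rows <- dplyr::bind_rows(rows, crows)
  }
  rows <- dplyr::arrange(rows, match(.data$ID, unique(ssrs$contig)), .data$start)
  rows <- dplyr::mutate(rows, nr = dplyr::row_number(), .after = "ID")
  readr::write_tsv(rows, path)
  invisible(path)
}
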