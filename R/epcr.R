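#' Locate exact full-length primer matches in an assembly
#'
#' Finds every occurrence of the primer (plus strand) and of its reverse
#' complement (minus strand) across all contigs. Matching is exact string
#' search at 100% identity over the full primer length; `N` in the subject
#' never matches.
#'
#' @param assembly an `ssr_assembly`.
#' @param primer primer sequence, 5'->3', length >= 10, `A`/`C`/`G`/`T`.
#' @return tibble with columns `contig`, `start`, `end` (1-based inclusive)
#'   and `strand` (`"+"`/`"-"`), sorted by contig file order then start.
#' @export
find_primer_sites <- function(assembly, primer) {
  stopifnot(nchar(primer) >= 10L, !grepl("[^ACGT]", primer))
  subject <- Biostrings::DNAStringSet(assembly$seq)
  hits <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, subject, fixed = TRUE)
    n_per <- lengths(m)
    if (sum(n_per) == 0L) return(NULL)
    ir <- unlist(m)
    tibble(contig = rep(names(assembly$seq), n_per),
           start = BiocGenerics::start(ir),
           end = BiocGenerics::end(ir),
           strand = strand)
  }
  res <- dplyr::bind_rows(hits(primer, "+"), hits(revcomp(primer), "-"))
  if (nrow(res) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  dplyr::arrange(res, match(.data$contig, names(assembly$seq)), .data$start,
                 .data$strand)
}

#' Amplify a primer pair in silico in one assembly
#'
#' Pairs every forward site with every reverse site on the same contig whose
#' 3' ends face inward: either the forward primer matches the plus strand
#' upstream of a minus-strand reverse-primer site (`orientation
#' "fwd_first"`), or the mirror arrangement (`"rev_first"`). The product
#' spans the left site's first base through the right site's last base
#' (primers included); products longer than `max_amplicon`, same-strand
#' co-occurrences, and overlapping sites never amplify. Identical spans are
#' deduplicated.
#'
#' @param assembly an `ssr_assembly`.
#' @param fwd,rev primer sequences, 5'->3'.
#' @param max_amplicon maximum product span in bp (default 1500).
#' @return tibble with columns `contig`, `start`, `end`, `length`,
#'   `orientation`, and `seq` (product sequence oriented forward-primer
#'   first), sorted by contig then start.
#' @export
amplify <- function(assembly, fwd, rev, max_amplicon = 1500L) {
  sf <- find_primer_sites(assembly, fwd)
  sr <- find_primer_sites(assembly, rev)
  pair_up <- function(left, right, orientation) {
    # left primer on plus strand, right primer on minus strand, inward
    l <- left[left$strand == "+", , drop = FALSE]
    r <- right[right$strand == "-", , drop = FALSE]
    if (nrow(l) == 0L || nrow(r) == 0L) return(NULL)
    g <- expand.grid(i = seq_len(nrow(l)), j = seq_len(nrow(r)))
    same <- l$contig[g$i] == r$contig[g$j]
    inward <- r$start[g$j] > l$end[g$i]
    span <- r$end[g$j] - l$start[g$i] + 1L
    keep <- same & inward & span <= max_amplicon
    if (!any(keep)) return(NULL)
    g <- g[keep, , drop = FALSE]
    tibble(contig = l$contig[g$i], start = l$start[g$i],
           end = r$end[g$j], length = r$end[g$j] - l$start[g$i] + 1L,
           orientation = orientation)
  }
  amps <- dplyr::bind_rows(pair_up(sf, sr, "fwd_first"),
                           pair_up(sr, sf, "rev_first"))
  if (nrow(amps) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  length = integer(), orientation = character(),
                  seq = character()))
  }
  amps <- dplyr::distinct(amps, .data$contig, .data$start, .data$end,
                          .keep_all = TRUE)
  amps <- dplyr::arrange(amps, match(.data$contig, names(assembly$seq)),
                         .data$start)
  amps$seq <- vapply(seq_len(nrow(amps)), function(i) {
    s <- extract_seq(assembly, amps$contig[i], amps$start[i], amps$end[i])
    if (amps$orientation[i] == "rev_first") revcomp(s) else s
  }, character(1))
  amps
}

#' Amplify all markers in all assemblies
#'
#' @param markers tibble from [design_markers()] (one row per marker).
#' @param assemblies list of `ssr_assembly` objects (paths are accepted).
#' @param max_amplicon maximum product span, bp.
#' @param threads markers are processed in parallel when > 1.
#' @return tibble: `marker_id`, `assembly`, amplicon columns as in
#'   [amplify()].
#' @export
amplify_markers <- function(markers, assemblies, max_amplicon = 1500L,
                            threads = 1L) {
  assemblies <- as_assembly_list(assemblies)
  rows <- map_threads(seq_len(nrow(markers)), function(i) {
    m <- markers[i, ]
    purrr::map_dfr(assemblies, function(a) {
      amps <- amplify(a, m$fwd, m$rev, max_amplicon)
      if (nrow(amps) == 0L) return(NULL)
      dplyr::mutate(amps, marker_id = m$marker_id, assembly = a$label,
                    .before = 1L)
    })
  }, threads = threads)
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) {
    res <- tibble(marker_id = character(), assembly = character(),
                  contig = character(), start = integer(), end = integer(),
                  length = integer(), orientation = character(),
                  seq = character())
  }
  res
}

#' Pair externally reported primer hits into amplicons
#'
#' Adapter for tabular hit files from an external short-sequence search
#' (e.g. columns query id, subject id, percent identity, alignment length,
#' subject start, subject end, strand). Hits are filtered to 100% identity
#' and full primer length, then run through the same inward-facing pairing
#' logic as [amplify()].
#'
#' @param hits data frame with columns `query`, `contig`, `identity`,
#'   `aln_len`, `start`, `end`, `strand` (`"+"`/`"-"`; `start` <= `end`).
#' @param fwd,rev the primer sequences the hits refer to (`query` must be
#'   `"fwd"` or `"rev"`).
#' @param max_amplicon maximum product span, bp.
#' @return tibble of amplicons (`contig`, `start`, `end`, `length`,
#'   `orientation`); no `seq` column since no assembly is at hand.
#' @export
pair_external_hits <- function(hits, fwd, rev, max_amplicon = 1500L) {
  lens <- c(fwd = nchar(fwd), rev = nchar(rev))
  hits <- hits[hits$identity >= 100 & hits$aln_len == lens[hits$query], ,
               drop = FALSE]
  sites <- function(q) {
    h <- hits[hits$query == q, , drop = FALSE]
    tibble(contig = as.character(h$contig), start = as.integer(h$start),
           end = as.integer(h$end), strand = as.character(h$strand))
  }
  sf <- sites("fwd"); sr <- sites("rev")
  pair_up <- function(left, right, orientation) {
    l <- left[left$strand == "+", , drop = FALSE]
    r <- right[right$strand == "-", , drop = FALSE]
    if (nrow(l) == 0L || nrow(r) == 0L) return(NULL)
    g <- expand.grid(i = seq_len(nrow(l)), j = seq_len(nrow(r)))
    keep <- l$contig[g$i] == r$contig[g$j] & r$start[g$j] > l$end[g$i] &
      (r$end[g$j] - l$start[g$i] + 1L) <= max_amplicon
    if (!any(keep)) return(NULL)
    g <- g[keep, , drop = FALSE]
    tibble(contig = l$contig[g$i], start = l$start[g$i], end = r$end[g$j],
           length = r$end[g$j] - l$start[g$i] + 1L,
           orientation = orientation)
  }
  amps <- dplyr::bind_rows(pair_up(sf, sr, "fwd_first"),
                           pair_up(sr, sf, "rev_first"))
  if (nrow(amps) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  length = integer(), orientation = character()))
  }
  amps |>
    dplyr::distinct(.data$contig, .data$start, .data$end, .keep_all = TRUE) |>
    dplyr::arrange(.data$contig, .data$start)
}
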