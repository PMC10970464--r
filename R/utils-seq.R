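#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Integer codes used by the scanners: A=1 C=2 G=3 T=4, N/other = NA.
.CODE <- {
  x <- rep(NA_integer_, 256)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x
}

seq_codes <- function(seq) .CODE[utf8ToInt(seq)]

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`; `N` is its own complement. Only `A`, `C`, `G`, `T`,
#' `N` are expected.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not a whole-number repetition of any
#' shorter motif (`"AT"` is, `"ATAT"` is not).
#'
#' @param motif character vector of motifs.
#' @return logical vector.
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n <= 1L) return(TRUE)
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L && strrep(substr(m, 1L, d), n %/% d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# All cyclic rotations of a single motif.
motif_rotations <- function(motif) {
  n <- nchar(motif)
  doubled <- paste0(motif, motif)
  unique(vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), character(1)))
}

#' Canonical motif label
#'
#' Returns the lexicographically smallest string among all cyclic rotations
#' of the motif and of its reverse complement. Used for reporting and
#' grouping only; marker selection compares motifs up to rotation on the
#' product strand, not up to reverse complement.
#'
#' @param motif character vector of primitive motifs (length 1-6).
#' @return character vector of canonical labels.
#' @export
#' @examples
#' normalize_motif(c("TA", "GA", "ATG"))
normalize_motif <- function(motif) {
  stopifnot(all(nchar(motif) >= 1L), all(nchar(motif) <= 6L))
  if (any(!is_primitive_motif(motif))) {
    abort("normalize_motif() requires primitive motifs")
  }
  vapply(motif, function(m) {
    min(c(motif_rotations(m), motif_rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

# Maximal perfect tandem runs of the given unit lengths in one sequence.
#
# Left-anchored complete-unit convention: a maximal stretch with period u
# starting at position i is reported as floor(len/u) complete units from i;
# the partial trailing unit extends the "stretch" but not the run interval.
# Runs whose left-anchored motif is non-primitive are dropped (the stretch
# is a run of a shorter unit and is reported there, when searched).
# Positions are 1-based inclusive. N matches nothing and splits runs.
#
# Returns tibble(start, end, stretch_start, stretch_end, motif, unit_len,
# repeats), sorted by start then unit_len. min_repeats = 2 guards against
# degenerate single-unit "runs".
tandem_runs <- function(seq, unit_lens) {
  n <- nchar(seq)
  code <- seq_codes(seq)
  out <- vector("list", length(unit_lens))
  for (k in seq_along(unit_lens)) {
    u <- unit_lens[k]
    if (n < 2L * u) next
    a <- code[seq_len(n - u)]
    b <- code[seq.int(u + 1L, n)]
    eq <- !is.na(a) & !is.na(b) & a == b
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= u
    if (!any(keep)) next
    i <- starts[keep]
    len <- r$lengths[keep] + u          # full periodic stretch length
    reps <- len %/% u
    motif <- substring(seq, i, i + u - 1L)
    prim <- is_primitive_motif(motif)
    if (!any(prim)) next
    out[[k]] <- tibble(
      start = i[prim],
      end = (i + reps * u - 1L)[prim],
      stretch_start = i[prim],
      stretch_end = (i + len - 1L)[prim],
      motif = motif[prim],
      unit_len = u,
      repeats = reps[prim]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(start = integer(), end = integer(),
                  stretch_start = integer(), stretch_end = integer(),
                  motif = character(), unit_len = integer(),
                  repeats = integer()))
  }
  dplyr::arrange(res, .data$start, .data$unit_len)
}

# Merge possibly-overlapping 1-based inclusive intervals given as a tibble
# with columns start, end; returns merged intervals sorted by start.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(tibble(start = integer(), end = integer()))
  df <- dplyr::arrange(df, .data$start, .data$end)
  s <- df$start; e <- df$end
  ms <- s[1]; me <- e[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Deterministic per-item map preserving input order; forks only when
# threads > 1 and the platform supports it. Results are identical for any
# thread count because mclapply returns in input order and no RNG is used
# inside pipeline steps.
map_threads <- function(x, f, threads = 1L) {
  if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(x, f, mc.cores = threads, mc.preschedule = TRUE)
  } else {
    lapply(x, f)
  }
}
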