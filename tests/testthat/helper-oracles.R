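# Independent oracles and sequence generators used across the suite.
# Each oracle deliberately uses a different mechanism from the package
# implementation it checks.

# Brute-force SSR scan: per unit length, walk every position left to right,
# count complete units by direct string comparison, accept when the
# left-anchored motif is primitive and the count meets the threshold, then
# resume after the accepted run.
oracle_find_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  n <- nchar(seq)
  out <- list()
  for (u in as.integer(names(thresholds))) {
    minr <- unclass(thresholds)[[as.character(u)]]
    pos <- 1L
    while (pos + u * minr - 1L <= n) {
      motif <- substr(seq, pos, pos + u - 1L)
      k <- 0L
      if (!grepl("N", motif) && is_primitive_motif(motif)) {
        j <- pos
        while (j + u - 1L <= n && substr(seq, j, j + u - 1L) == motif) {
          k <- k + 1L
          j <- j + u
        }
      }
      if (k >= minr) {
        out[[length(out) + 1L]] <- tibble::tibble(
          start = pos, end = pos + k * u - 1L, motif = motif,
          unit_len = u, repeats = k)
        pos <- pos + k * u
      } else {
        pos <- pos + 1L
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          motif = character(), unit_len = integer(),
                          repeats = integer()))
  }
  dplyr::arrange(res, start, unit_len)
}

# Random sequence enriched with planted repeat runs, partial units and Ns,
# so the mining comparison is not vacuously empty.
random_repeatish_seq <- function(n_target, seed) {
  set.seed(seed)
  parts <- character()
  total <- 0L
  motifs <- c("A", "T", "AT", "AC", "AG", "CT", "ATG", "AAG", "CTG",
              "AAT", "ACGT", "AATG")
  while (total < n_target) {
    if (stats::runif(1) < 0.55) {
      len <- sample(20:120, 1)
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    } else {
      m <- sample(motifs, 1)
      reps <- sample(2:15, 1)
      s <- strrep(m, reps)
      if (stats::runif(1) < 0.3) {          # partial trailing unit
        s <- paste0(s, substr(m, 1, max(1L, nchar(m) - 1L)))
      }
      if (stats::runif(1) < 0.1) s <- paste0(s, "N")
    }
    parts <- c(parts, s)
    total <- total + nchar(s)
  }
  substr(paste(parts, collapse = ""), 1L, n_target)
}

# Naive O(n*m) primer-site scan by direct substring comparison.
oracle_sites <- function(assembly, primer) {
  m <- nchar(primer)
  rc <- revcomp(primer)
  out <- list()
  for (cn in names(assembly$seq)) {
    s <- assembly$seq[[cn]]
    n <- nchar(s)
    if (n < m) next
    starts <- seq_len(n - m + 1L)
    win <- substring(s, starts, starts + m - 1L)
    for (st in c("+", "-")) {
      hit <- starts[win == if (st == "+") primer else rc]
      if (length(hit) > 0L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          contig = cn, start = hit, end = hit + m - 1L, strand = st)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  dplyr::arrange(res, match(contig, names(assembly$seq)), start, strand)
}

# Brute-force amplicon pairing from oracle sites: every inward-facing
# combination within the span limit, deduplicated.
oracle_amplify <- function(assembly, fwd, rev, max_amplicon = 1500L) {
  sf <- oracle_sites(assembly, fwd)
  sr <- oracle_sites(assembly, rev)
  out <- list()
  combos <- list(list(l = sf, r = sr), list(l = sr, r = sf))
  for (cb in combos) {
    l <- cb$l[cb$l$strand == "+", , drop = FALSE]
    r <- cb$r[cb$r$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(l))) {
      for (j in seq_len(nrow(r))) {
        if (l$contig[i] != r$contig[j]) next
        if (r$start[j] <= l$end[i]) next
        span <- r$end[j] - l$start[i] + 1L
        if (span > max_amplicon) next
        out[[length(out) + 1L]] <- tibble::tibble(
          contig = l$contig[i], start = l$start[i], end = r$end[j])
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer()))
  }
  dplyr::distinct(dplyr::arrange(res, contig, start, end))
}

# Exhaustive primer-pair search over a region using the exported per-window
# statistics, independent of the vectorised window enumerator.
oracle_design <- function(region, ssr_start, ssr_end, cfg = design_config()) {
  windows <- function(lo, hi) {
    out <- list()
    for (L in cfg$size_min:cfg$size_max) {
      if (hi - lo + 1L < L) next
      for (st in lo:(hi - L + 1L)) {
        w <- substr(region, st, st + L - 1L)
        if (grepl("N", w)) next
        if (max_mono_run(w) > cfg$max_mono_run) next
        g <- gc_content(w)
        if (g < cfg$gc_min || g > cfg$gc_max) next
        tm <- melting_temp(w)
        if (tm < cfg$tm_min || tm > cfg$tm_max) next
        out[[length(out) + 1L]] <- tibble::tibble(
          start = st, end = st + L - 1L, seq = w, tm = tm)
      }
    }
    dplyr::bind_rows(out)
  }
  fw <- windows(1L, ssr_start - 1L)
  rv <- windows(ssr_end + 1L, nchar(region))
  if (nrow(fw) == 0L || nrow(rv) == 0L) return(NULL)
  best <- NULL
  mid <- (cfg$product_min + cfg$product_max) / 2
  for (i in seq_len(nrow(fw))) {
    for (j in seq_len(nrow(rv))) {
      pl <- rv$end[j] - fw$start[i] + 1L
      if (pl < cfg$product_min || pl > cfg$product_max) next
      pen <- abs(fw$tm[i] - cfg$tm_opt) + abs(rv$tm[j] - cfg$tm_opt) +
        abs(fw$tm[i] - rv$tm[j]) + 0.05 * abs(pl - mid)
      cand <- list(pen = pen, fwd_start = fw$start[i], product = pl,
                   fwd = fw$seq[i], rev = revcomp(rv$seq[j]))
      if (is.null(best) ||
          pen < best$pen - 1e-12 ||
          (abs(pen - best$pen) <= 1e-12 &&
           (cand$fwd_start < best$fwd_start ||
            (cand$fwd_start == best$fwd_start && pl < best$product)))) {
        best <- cand
      }
    }
  }
  best
}

# Small clean fixture helpers reused by several files.
tiny_fixture <- function(seed = 7L, n_assemblies = 2L) {
  generate_assemblies(
    n_assemblies = n_assemblies,
    counts = c(polymorphic_unique = 4L, monomorphic = 1L, flank_indel = 1L,
               duplicated = 1L, composite_decoy = 1L, near_end_decoy = 1L,
               near_ssr_decoy = 1L, low_complexity_decoy = 1L,
               too_far_decoy = 1L),
    seed = seed)
}

# Map pipeline marker verdicts back onto truth loci by interval overlap on
# the mining assembly.
match_truth <- function(res, truth) {
  truth_a <- truth[truth$assembly == "asm1" & truth$part == 1L &
                     truth$copy == 1L, , drop = FALSE]
  td <- tidy(res)
  m <- merge(td, truth_a, by = "contig")
  m[m$ssr_start <= m$end & m$ssr_end >= m$start, , drop = FALSE]
}
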