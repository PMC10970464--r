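# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K); 16 stacks indexed (first-1)*4 + second with
# A=1 C=2 G=3 T=4, i.e. order AA AC AG AT CA CC CG CT GA GC GG GT TA TC TG TT.
.NN_DH <- c(-7.9, -8.4, -7.8, -7.2,
            -8.5, -8.0, -10.6, -7.8,
            -8.2, -9.8, -8.0, -8.4,
            -7.2, -8.2, -8.5, -7.9)
.NN_DS <- c(-22.2, -22.4, -21.0, -20.4,
            -22.7, -19.9, -27.2, -21.0,
            -22.2, -24.4, -19.9, -22.4,
            -21.3, -22.2, -22.7, -22.2)
.R_GAS <- 1.987  # cal/(mol K)

#' GC content of a sequence
#'
#' @param seq character vector of `A`/`C`/`G`/`T` sequences.
#' @return numeric vector, percent GC (0-100).
#' @export
#' @examples
#' gc_content(c("ATGC", "GGCC", "ATAT"))
gc_content <- function(seq) {
  stopifnot(all(nchar(seq) > 0L))
  if (any(grepl("[^ACGT]", seq))) abort("gc_content() accepts A/C/G/T only")
  100 * stringr::str_count(seq, "[GC]") / nchar(seq)
}

#' Longest mononucleotide run
#'
#' @param seq character vector.
#' @return integer vector: length of the longest single-letter run in each
#'   sequence.
#' @export
#' @examples
#' max_mono_run(c("AAAAT", "ACGT", "CGGGGGA"))
max_mono_run <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return(0L)
    max(rle(strsplit(s, "")[[1]])$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm under the SantaLucia (1998) unified nearest-neighbor
#' parameters with the common primer-design default conditions: 50 mM
#' monovalent cation, no divalent cations or dNTPs, 50 nM total oligo.
#' Entropy is salt-corrected by `0.368 (L-1) ln[Na+]` and
#' `Tm = 1000 dH / (dS + R ln(CT/x)) - 273.15` with `x = 4` for
#' non-self-complementary sequences (`x = 1` when the sequence equals its
#' reverse complement). Deterministic; duplex symmetry holds exactly
#' (`melting_temp(revcomp(s)) == melting_temp(s)`).
#'
#' @param seq character vector of sequences, length 10-36, `A`/`C`/`G`/`T`
#'   only.
#' @param na_mM monovalent cation concentration, mM.
#' @param ct_nM total single-strand concentration, nM.
#' @return numeric vector of Tm in degrees Celsius.
#' @export
melting_temp <- function(seq, na_mM = 50, ct_nM = 50) {
  if (any(nchar(seq) < 10L | nchar(seq) > 36L)) {
    abort("melting_temp() requires sequence length 10-36")
  }
  if (any(grepl("[^ACGT]", seq))) abort("melting_temp() accepts A/C/G/T only")
  vapply(seq, function(s) {
    code <- seq_codes(s)
    L <- length(code)
    idx <- (code[-L] - 1L) * 4L + code[-1L]
    dh <- sum(.NN_DH[idx])
    ds <- sum(.NN_DS[idx])
    for (term in code[c(1L, L)]) {
      if (term == 2L || term == 3L) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    x <- 4
    if (s == revcomp(s)) { ds <- ds - 1.4; x <- 1 }
    ds <- ds + 0.368 * (L - 1) * log(na_mM / 1000)
    1000 * dh / (ds + .R_GAS * log(ct_nM * 1e-9 / x)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer-design configuration
#'
#' Hard constraints follow common microsatellite-marker design practice:
#' product 100-250 bp, primer 19-23 bp, Tm 58-62 degrees C, GC 40-60 %, at
#' most 4 identical consecutive bases. The ranking penalty is
#' `w_tm (|Tm_f - tm_opt| + |Tm_r - tm_opt| + |Tm_f - Tm_r|) +
#'  w_product |product - (product_min + product_max)/2|`.
#'
#' @param product_min,product_max product length bounds, bp.
#' @param n_results maximum pairs returned per region.
#' @param size_min,size_max primer length bounds, bp.
#' @param size_opt nominal primer length (reported in configs for
#'   interoperability; the ranking uses Tm and product terms only).
#' @param tm_min,tm_max,tm_opt melting temperature bounds and optimum, deg C.
#' @param gc_min,gc_max GC bounds, percent.
#' @param max_mono_run maximum mononucleotide run inside a primer.
#' @param w_tm,w_product penalty weights (deg C and bp deviations).
#' @param self_screen when `TRUE`, candidates whose longest
#'   self-complementary stretch exceeds `self_max` are discarded.
#' @param self_max see `self_screen`.
#' @return a list of class `design_config`.
#' @export
design_config <- function(product_min = 100L, product_max = 250L,
                          n_results = 1L,
                          size_min = 19L, size_max = 23L, size_opt = 21L,
                          tm_min = 58, tm_max = 62, tm_opt = 60,
                          gc_min = 40, gc_max = 60,
                          max_mono_run = 4L,
                          w_tm = 1, w_product = 0.05,
                          self_screen = FALSE, self_max = 8L) {
  stopifnot(size_min <= size_opt, size_opt <= size_max,
            tm_min <= tm_opt, tm_opt <= tm_max,
            product_min <= product_max, gc_min <= gc_max)
  structure(as.list(environment()), class = "design_config")
}

# All primer-length windows of `seq` with vectorised Tm/GC/mono-run stats.
# Windows containing N get has_n = TRUE and NA stats.
primer_windows <- function(seq, cfg) {
  n <- nchar(seq)
  code <- seq_codes(seq)
  idx <- (code[-n] - 1L) * 4L + code[-1L]
  dh0 <- c(0, cumsum(ifelse(is.na(idx), 0, .NN_DH[idx])))
  ds0 <- c(0, cumsum(ifelse(is.na(idx), 0, .NN_DS[idx])))
  na0 <- c(0L, cumsum(is.na(code)))
  gc0 <- c(0L, cumsum(!is.na(code) & (code == 2L | code == 3L)))
  eq <- !is.na(code[-n]) & !is.na(code[-1L]) & code[-n] == code[-1L]
  eq0 <- c(0L, cumsum(eq))
  run_bad <- cfg$max_mono_run  # run of max_mono_run+1 letters = run_bad equal pairs
  # positions k where letters k..k+run_bad are all equal (run > max allowed)
  b0 <- NULL
  if (n > run_bad) {
    kk <- seq_len(n - run_bad)
    run_start <- (eq0[kk + run_bad] - eq0[kk]) == run_bad
    b0 <- c(0L, cumsum(tabulate(which(run_start), nbins = n)))
  }
  out <- vector("list", cfg$size_max - cfg$size_min + 1L)
  for (L in cfg$size_min:cfg$size_max) {
    if (n < L) next
    s <- seq_len(n - L + 1L)
    e <- s + L - 1L
    has_n <- (na0[e + 1L] - na0[s]) > 0L
    mono_bad <- rep(FALSE, length(s))
    if (!is.null(b0)) {
      hi <- pmax(e - run_bad, 0L)
      cnt <- ifelse(hi >= s, b0[hi + 1L] - b0[s], 0L)
      mono_bad <- cnt > 0L
    }
    dh <- dh0[e] - dh0[s]
    ds <- ds0[e] - ds0[s]
    first <- code[s]; last <- code[e]
    init_gc_f <- !is.na(first) & (first == 2L | first == 3L)
    init_gc_l <- !is.na(last) & (last == 2L | last == 3L)
    dh <- dh + ifelse(init_gc_f, 0.1, 2.3) + ifelse(init_gc_l, 0.1, 2.3)
    ds <- ds + ifelse(init_gc_f, -2.8, 4.1) + ifelse(init_gc_l, -2.8, 4.1)
    wseq <- substring(seq, s, e)
    selfc <- if (L %% 2L == 0L) wseq == revcomp(wseq) else rep(FALSE, length(s))
    ds <- ds + ifelse(selfc, -1.4, 0) + 0.368 * (L - 1) * log(50 / 1000)
    tm <- 1000 * dh / (ds + .R_GAS * log(50e-9 / ifelse(selfc, 1, 4))) - 273.15
    gc <- 100 * (gc0[e + 1L] - gc0[s]) / L
    tm[has_n] <- NA_real_; gc[has_n] <- NA_real_
    out[[L - cfg$size_min + 1L]] <- tibble(
      start = s, end = e, len = L, seq = wseq,
      tm = tm, gc = gc, mono_bad = mono_bad, has_n = has_n
    )
  }
  dplyr::bind_rows(out)
}

# Longest self-complementary stretch: largest k such that some k-mer of the
# primer also occurs reverse-complemented within the primer.
longest_selfcomp <- function(seq) {
  n <- nchar(seq)
  for (k in seq.int(n, 1L)) {
    kmers <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    if (any(revcomp(kmers) %in% kmers)) return(k)
  }
  0L
}

#' Design primer pairs for one promising SSR region
#'
#' Exhaustively enumerates candidate forward windows in the upstream flank
#' and reverse windows in the downstream flank (all lengths
#' `size_min..size_max`) that individually satisfy the Tm/GC/mono-run
#' constraints and contain no `N`, pairs them subject to the product-length
#' bounds (the product spans the forward primer's first base through the
#' reverse primer's site, both primers included, and always contains the
#' whole SSR), ranks pairs by penalty and returns the best `n_results`.
#' Ties break by leftmost forward position, then shortest product.
#'
#' @param region_seq region sequence (upstream flank + SSR + downstream
#'   flank) as a single string.
#' @param ssr_start,ssr_end 1-based inclusive SSR coordinates within
#'   `region_seq`.
#' @param cfg a [design_config()].
#' @return tibble with 0 to `n_results` rows: `fwd`, `rev` (both 5'->3'),
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (plus-strand window of
#'   the reverse primer, region coordinates), `tm_f`, `tm_r`, `gc_f`,
#'   `gc_r`, `product_len`, `penalty`.
#' @export
design_primers <- function(region_seq, ssr_start, ssr_end,
                           cfg = design_config()) {
  w <- primer_windows(region_seq, cfg)
  ok <- !w$has_n & !w$mono_bad &
    !is.na(w$tm) & w$tm >= cfg$tm_min & w$tm <= cfg$tm_max &
    w$gc >= cfg$gc_min & w$gc <= cfg$gc_max
  w <- w[which(ok), , drop = FALSE]
  fw <- w[w$end <= ssr_start - 1L, , drop = FALSE]
  rv <- w[w$start >= ssr_end + 1L, , drop = FALSE]
  empty <- tibble(fwd = character(), rev = character(),
                  fwd_start = integer(), fwd_end = integer(),
                  rev_start = integer(), rev_end = integer(),
                  tm_f = numeric(), tm_r = numeric(),
                  gc_f = numeric(), gc_r = numeric(),
                  product_len = integer(), penalty = numeric())
  if (nrow(fw) == 0L || nrow(rv) == 0L) return(empty)
  if (cfg$self_screen) {
    fw <- fw[vapply(fw$seq, longest_selfcomp, integer(1)) <= cfg$self_max, ,
             drop = FALSE]
    rv <- rv[vapply(rv$seq, longest_selfcomp, integer(1)) <= cfg$self_max, ,
             drop = FALSE]
    if (nrow(fw) == 0L || nrow(rv) == 0L) return(empty)
  }
  grid <- expand.grid(i = seq_len(nrow(fw)), j = seq_len(nrow(rv)))
  prod_len <- rv$end[grid$j] - fw$start[grid$i] + 1L
  keep <- prod_len >= cfg$product_min & prod_len <= cfg$product_max
  if (!any(keep)) return(empty)
  grid <- grid[keep, , drop = FALSE]
  prod_len <- prod_len[keep]
  mid <- (cfg$product_min + cfg$product_max) / 2
  tmf <- fw$tm[grid$i]; tmr <- rv$tm[grid$j]
  penalty <- cfg$w_tm * (abs(tmf - cfg$tm_opt) + abs(tmr - cfg$tm_opt) +
                           abs(tmf - tmr)) +
    cfg$w_product * abs(prod_len - mid)
  ord <- order(penalty, fw$start[grid$i], prod_len)
  take <- ord[seq_len(min(cfg$n_results, length(ord)))]
  tibble(
    fwd = fw$seq[grid$i[take]],
    rev = revcomp(rv$seq[grid$j[take]]),
    fwd_start = fw$start[grid$i[take]],
    fwd_end = fw$end[grid$i[take]],
    rev_start = rv$start[grid$j[take]],
    rev_end = rv$end[grid$j[take]],
    tm_f = tmf[take], tm_r = tmr[take],
    gc_f = fw$gc[grid$i[take]], gc_r = rv$gc[grid$j[take]],
    product_len = prod_len[take],
    penalty = penalty[take]
  )
}

#' Design primers for every promising region of an assembly
#'
#' Extracts a `flank` bp window on each side of every promising SSR and runs
#' [design_primers()]. One marker row is produced per returned pair; regions
#' where no pair satisfies the constraints are absent from the result (the
#' pipeline books them as "without suitable primers").
#'
#' @param regions tibble from [analyze_regions()], typically filtered to
#'   `status == "promising"` (other statuses are dropped here too).
#' @param assembly the source `ssr_assembly`.
#' @param cfg a [design_config()].
#' @param flank flank window per side, bp; must not exceed the guaranteed
#'   separation from [region_config()].
#' @param threads regions are processed in parallel when > 1.
#' @return tibble with one row per designed pair: `marker_id`
#'   (`contig:start-end` of the SSR), SSR columns, primer columns as in
#'   [design_primers()] but in contig coordinates, and `product_start`,
#'   `product_end`.
#' @export
design_markers <- function(regions, assembly, cfg = design_config(),
                           flank = 200L, threads = 1L) {
  regions <- regions[regions$status == "promising", , drop = FALSE]
  rows <- map_threads(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    off <- r$start - flank - 1L  # region-local 1 == contig off+1
    rs <- extract_seq(assembly, r$contig, r$start - flank, r$end + flank)
    pairs <- design_primers(rs, flank + 1L, flank + r$length, cfg)
    if (nrow(pairs) == 0L) return(NULL)
    tibble(
      marker_id = paste0(r$contig, ":", r$start, "-", r$end),
      contig = r$contig, ssr_start = r$start, ssr_end = r$end,
      motif = r$motif, unit_len = r$unit_len, repeats = r$repeats,
      fwd = pairs$fwd, rev = pairs$rev,
      fwd_start = pairs$fwd_start + off, fwd_end = pairs$fwd_end + off,
      rev_start = pairs$rev_start + off, rev_end = pairs$rev_end + off,
      tm_f = pairs$tm_f, tm_r = pairs$tm_r,
      gc_f = pairs$gc_f, gc_r = pairs$gc_r,
      product_len = pairs$product_len,
      product_start = pairs$fwd_start + off,
      product_end = pairs$rev_end + off,
      penalty = pairs$penalty
    )
  }, threads = threads)
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) {
    res <- tibble(marker_id = character(), contig = character(),
                  ssr_start = integer(), ssr_end = integer(),
                  motif = character(), unit_len = integer(),
                  repeats = integer(), fwd = character(), rev = character(),
                  fwd_start = integer(), fwd_end = integer(),
                  rev_start = integer(), rev_end = integer(),
                  tm_f = numeric(), tm_r = numeric(),
                  gc_f = numeric(), gc_r = numeric(),
                  product_len = integer(), product_start = integer(),
                  product_end = integer(), penalty = numeric())
  }
  res
}
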