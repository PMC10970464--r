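# Planted-truth fixture generator: multi-assembly FASTA with homologous SSR
# loci under controlled repeat-length divergence, plus decoy classes that
# must die at known pipeline stages.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# no tandem stretch of >= max_stretch bp anywhere (keeps spacers/flanks free
# of accidental minable SSRs and of extra low-complexity flags)
is_clean_dna <- function(seq, max_stretch = 12L) {
  runs <- tandem_runs(seq, 1:6)
  all(runs$stretch_end - runs$stretch_start + 1L < max_stretch)
}

clean_dna <- function(n, gc = 0.5, max_stretch = 12L, tries = 200L) {
  for (i in seq_len(tries)) {
    s <- random_dna(n, gc)
    if (is_clean_dna(s, max_stretch)) return(s)
  }
  abort("could not sample clean background sequence")
}

.LOCUS_CLASSES <- c("polymorphic_unique", "monomorphic", "flank_indel",
                    "duplicated", "composite_decoy", "near_end_decoy",
                    "near_ssr_decoy", "low_complexity_decoy", "too_far_decoy")

.CLASS_FATE <- c(polymorphic_unique = "selected",
                 monomorphic = "monomorphic",
                 flank_indel = "flank_variation",
                 duplicated = "multi_site",
                 composite_decoy = "composite",
                 near_end_decoy = "near_contig_end",
                 near_ssr_decoy = "near_ssr",
                 low_complexity_decoy = "extra_low_complexity",
                 too_far_decoy = "absent")

.CLASS_STAGE <- c(polymorphic_unique = "selected",
                  monomorphic = "step6", flank_indel = "step6",
                  duplicated = "step6", composite_decoy = "step2",
                  near_end_decoy = "step2", near_ssr_decoy = "step2",
                  low_complexity_decoy = "step4", too_far_decoy = "step6")

# expected set of runs with stretch >= 12 bp in a locus region, as exact
# complete-unit coordinates; used to verify junction cleanliness
expect_exact_runs <- function(region, expected) {
  runs <- tandem_runs(region, 1:6)
  long <- runs[runs$stretch_end - runs$stretch_start + 1L >= 12L, ,
               drop = FALSE]
  long <- long[order(long$start), , drop = FALSE]
  nrow(long) == nrow(expected) &&
    all(long$start == expected$start) && all(long$end == expected$end)
}

# Draw one locus' shared material; returns NULL if rejection fails.
draw_locus <- function(class, n_assemblies, flank, cfg_design, gc) {
  di <- stats::runif(1) < 0.6
  motif <- if (di) sample(c("AT", "AC", "AG", "CT", "GT", "GA"), 1) else
    sample(c("ATC", "AAG", "ACC", "AGG", "ATG", "CTG", "AAC", "TTG"), 1)
  u <- nchar(motif)
  rep_a <- if (di) sample(10:14, 1) else sample(7:10, 1)
  reps <- rep(rep_a, n_assemblies)
  if (class %in% c("polymorphic_unique", "flank_indel", "duplicated",
                   "too_far_decoy", "low_complexity_decoy")) {
    deltas <- sample(setdiff(-3:4, 0), n_assemblies - 1L)
    reps[-1] <- pmax(rep_a + deltas, 6L)
    if (length(unique(reps)) == 1L) reps[2] <- reps[2] + 1L
  }
  if (class == "too_far_decoy") reps[2] <- as.integer(ceiling(1700 / u))
  ssr <- function(k) strrep(motif, k)

  for (attempt in 1:300) {
    if (class == "near_end_decoy") {
      fl_l <- clean_dna(80L, gc); fl_r <- clean_dna(400L, gc)
      region_a <- paste0(fl_l, ssr(rep_a), fl_r)
      exp <- tibble(start = 81L, end = 80L + rep_a * u)
      if (!expect_exact_runs(region_a, exp)) next
      return(list(motif = motif, u = u, reps = reps, fl_l = fl_l,
                  fl_r = fl_r, gap = NULL, motif2 = NULL, reps2 = NULL,
                  indel = NULL))
    }
    if (class %in% c("composite_decoy", "near_ssr_decoy")) {
      gap_len <- if (class == "composite_decoy") 50L else 150L
      motif2 <- if (nchar(motif) == 2L) sample(c("ATG", "AAG", "CTG"), 1) else
        sample(c("AT", "AC", "AG"), 1)
      u2 <- nchar(motif2)
      rep2 <- if (u2 == 2L) sample(10:13, 1) else sample(7:9, 1)
      fl_l <- clean_dna(flank, gc); fl_r <- clean_dna(flank, gc)
      gap_seq <- clean_dna(gap_len, gc)
      region_a <- paste0(fl_l, ssr(rep_a), gap_seq, strrep(motif2, rep2), fl_r)
      s1 <- flank + 1L; e1 <- flank + rep_a * u
      s2 <- e1 + gap_len + 1L; e2 <- s2 + rep2 * u2 - 1L
      exp <- tibble(start = c(s1, s2), end = c(e1, e2))
      if (!expect_exact_runs(region_a, exp)) next
      return(list(motif = motif, u = u, reps = reps, fl_l = fl_l,
                  fl_r = fl_r, gap = gap_seq, motif2 = motif2,
                  reps2 = rep2, indel = NULL))
    }
    # classes that must admit primers
    if (class == "low_complexity_decoy") {
      pre <- clean_dna(flank - 30L, gc)
      mid <- clean_dna(10L, gc)
      if (substr(pre, flank - 30L, flank - 30L) == "A" ||
          substr(mid, 1L, 1L) == "A" ||
          substr(mid, 10L, 10L) == substr(motif, 1L, 1L)) next
      fl_l <- paste0(pre, strrep("A", 20L), mid)
    } else {
      fl_l <- clean_dna(flank, gc)
    }
    fl_r <- clean_dna(flank, gc)
    region_a <- paste0(fl_l, ssr(rep_a), fl_r)
    s1 <- flank + 1L; e1 <- flank + rep_a * u
    exp <- tibble(start = s1, end = e1)
    if (class == "low_complexity_decoy") {
      exp <- tibble(start = c(flank - 29L, s1), end = c(flank - 10L, e1))
    }
    if (!expect_exact_runs(region_a, exp)) next
    design_seq <- substr(region_a, flank - 200L + 1L,
                         flank + rep_a * u + 200L)
    pairs <- design_primers(design_seq, 201L, 200L + rep_a * u, cfg_design)
    if (nrow(pairs) == 0L) next
    indel <- NULL
    if (class == "flank_indel") {
      found <- FALSE
      for (cand in c("CGAT", "GCAC", "TCGA", "CTAG", "GACT")) {
        region_b <- paste0(fl_l, cand, ssr(reps[2]), fl_r)
        exp_b <- tibble(start = flank + 5L, end = flank + 4L + reps[2] * u)
        if (expect_exact_runs(region_b, exp_b)) {
          indel <- cand; found <- TRUE; break
        }
      }
      if (!found) next
    }
    return(list(motif = motif, u = u, reps = reps, fl_l = fl_l,
                fl_r = fl_r, gap = NULL, motif2 = NULL, reps2 = NULL,
                indel = indel))
  }
  NULL
}

# Locus region string + planted SSR coordinates for assembly `ai` (1-based
# within the region).
locus_region <- function(loc, class, ai) {
  u <- loc$u
  reps_i <- loc$reps[ai]
  fl <- nchar(loc$fl_l)
  if (class %in% c("composite_decoy", "near_ssr_decoy")) {
    u2 <- nchar(loc$motif2)
    seq <- paste0(loc$fl_l, strrep(loc$motif, reps_i), loc$gap,
                  strrep(loc$motif2, loc$reps2), loc$fl_r)
    s1 <- fl + 1L; e1 <- fl + reps_i * u
    s2 <- e1 + nchar(loc$gap) + 1L; e2 <- s2 + loc$reps2 * u2 - 1L
    return(list(seq = seq,
                parts = tibble(part = 1:2, motif = c(loc$motif, loc$motif2),
                               start = c(s1, s2), end = c(e1, e2),
                               repeats = c(reps_i, loc$reps2))))
  }
  ins <- if (class == "flank_indel" && ai == 2L) loc$indel else ""
  seq <- paste0(loc$fl_l, ins, strrep(loc$motif, reps_i), loc$fl_r)
  s1 <- fl + nchar(ins) + 1L; e1 <- s1 + reps_i * u - 1L
  list(seq = seq,
       parts = tibble(part = 1L, motif = loc$motif, start = s1, end = e1,
                      repeats = reps_i))
}

#' Generate planted-truth multi-assembly fixtures
#'
#' Builds `n_assemblies` homologous assemblies: uniform-composition random
#' background (GC fraction `gc`) with planted SSR loci sharing identical
#' flanks across assemblies, plus a machine-readable truth table stating
#' each locus' class, per-assembly coordinates and expected pipeline fate.
#' Classes: `polymorphic_unique` (repeat counts differ; must be selected),
#' `monomorphic`, `flank_indel` (4 bp insertion in one flank of assembly 2),
#' `duplicated` (second identical copy in assembly 2), `composite_decoy`
#' (two runs 50 bp apart), `near_end_decoy` (80 bp from its contig start),
#' `near_ssr_decoy` (second minable run 150 bp away), `low_complexity_decoy`
#' (A-homopolymer of 20 bp inside the product, 10 bp from the SSR) and
#' `too_far_decoy` (repeat growth in assembly 2 pushes the product beyond
#' 1500 bp). Flanks are rejection-sampled until the planted run is detected
#' at exactly its planted coordinates, no other >= 12 bp tandem stretch
#' exists in the region, and (for classes that must reach in silico PCR) at
#' least one primer pair satisfying `cfg_design` exists. Deterministic for
#' a fixed seed; each locus consumes an independent seeded stream so class
#' counts can change without reshuffling other loci.
#'
#' @param n_assemblies number of assemblies, >= 2.
#' @param counts named integer vector of loci per class (any subset of the
#'   classes above).
#' @param seed master seed.
#' @param dir when given, FASTA files (`asm1.fa`, ...) and `truth.tsv` are
#'   written there.
#' @param flank shared flank length per side, bp.
#' @param spacer background spacer between loci, bp.
#' @param gc background GC fraction (0.5 keeps primer constraints typically
#'   satisfiable).
#' @param cfg_design [design_config()] used for the feasibility check.
#' @return list with `assemblies` (list of `ssr_assembly`), `truth`
#'   (tibble: `locus_id`, `class`, `part`, `assembly`, `contig`, `start`,
#'   `end`, `motif`, `repeats`, `copy`, `expected_fate`, `expected_stage`)
#'   and, when `dir` is given, `paths`.
#' @export
generate_assemblies <- function(n_assemblies = 2L,
                                counts = c(polymorphic_unique = 20L,
                                           monomorphic = 5L,
                                           flank_indel = 5L,
                                           duplicated = 5L,
                                           composite_decoy = 5L,
                                           near_end_decoy = 5L,
                                           near_ssr_decoy = 5L,
                                           low_complexity_decoy = 5L,
                                           too_far_decoy = 5L),
                                seed = 1L, dir = NULL,
                                flank = 250L, spacer = 500L, gc = 0.5,
                                cfg_design = design_config()) {
  if (n_assemblies < 2L) abort("need at least 2 assemblies")
  if (is.null(names(counts)) || !all(names(counts) %in% .LOCUS_CLASSES)) {
    abort(paste("counts must be named with classes:",
                paste(.LOCUS_CLASSES, collapse = ", ")))
  }
  if (any(counts < 0L)) abort("counts must be nonnegative")
  seed <- as.integer(seed) %% 100000L
  for (salt in 0:4) {
    res <- build_fixture(n_assemblies, counts, seed + salt * 7919L,
                         flank, spacer, gc, cfg_design)
    if (!is.null(res)) break
  }
  if (is.null(res)) abort("fixture generation failed validation")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    res$paths <- vapply(res$assemblies, function(a) {
      p <- file.path(dir, paste0(a$label, ".fa"))
      write_assembly(a, p)
      p
    }, character(1))
    readr::write_tsv(res$truth, file.path(dir, "truth.tsv"))
  }
  res
}

build_fixture <- function(n_assemblies, counts, seed, flank, spacer, gc,
                          cfg_design) {
  classes <- rep(names(counts), counts)
  n_loci <- length(classes)
  loci <- vector("list", n_loci)
  for (j in seq_len(n_loci)) {
    loci[[j]] <- with_seed(seed * 131L + j * 977L, {
      draw_locus(classes[j], n_assemblies, flank, cfg_design, gc)
    })
    if (is.null(loci[[j]])) return(NULL)
  }
  locus_ids <- sprintf("L%03d", seq_len(n_loci))
  labels <- paste0("asm", seq_len(n_assemblies))
  main <- which(classes != "near_end_decoy")
  truth <- list()
  assemblies <- vector("list", n_assemblies)
  for (ai in seq_len(n_assemblies)) {
    parts <- character(); cursor <- 0L
    add <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      cursor <<- cursor + nchar(s)
    }
    add(with_seed(seed * 313L + ai * 101L, clean_dna(spacer, gc)))
    for (j in main) {
      lr <- locus_region(loci[[j]], classes[j], ai)
      truth[[length(truth) + 1L]] <- dplyr::mutate(
        lr$parts, locus_id = locus_ids[j], class = classes[j],
        assembly = labels[ai], contig = "chr1",
        start = .data$start + cursor, end = .data$end + cursor, copy = 1L)
      add(lr$seq)
      add(with_seed(seed * 313L + ai * 101L + j * 37L, clean_dna(spacer, gc)))
    }
    if (ai == 2L) {
      for (j in main[classes[main] == "duplicated"]) {
        lr <- locus_region(loci[[j]], classes[j], ai)
        truth[[length(truth) + 1L]] <- dplyr::mutate(
          lr$parts, locus_id = locus_ids[j], class = classes[j],
          assembly = labels[ai], contig = "chr1",
          start = .data$start + cursor, end = .data$end + cursor, copy = 2L)
        add(lr$seq)
        add(with_seed(seed * 313L + ai * 101L + j * 37L + 13L,
                      clean_dna(spacer, gc)))
      }
    }
    seqs <- c(chr1 = paste(parts, collapse = ""))
    for (j in which(classes == "near_end_decoy")) {
      lr <- locus_region(loci[[j]], classes[j], ai)
      cname <- paste0("ne_", locus_ids[j])
      truth[[length(truth) + 1L]] <- dplyr::mutate(
        lr$parts, locus_id = locus_ids[j], class = classes[j],
        assembly = labels[ai], contig = cname,
        copy = 1L)
      seqs[[cname]] <- lr$seq
    }
    assemblies[[ai]] <- new_assembly(seqs, labels[ai])
  }
  if (length(truth) == 0L) {
    truth <- tibble(locus_id = character(), class = character(),
                    part = integer(), copy = integer(),
                    assembly = character(), contig = character(),
                    start = integer(), end = integer(), motif = character(),
                    repeats = integer(), expected_fate = character(),
                    expected_stage = character())
    return(list(assemblies = assemblies, truth = truth))
  }
  truth <- dplyr::bind_rows(truth) |>
    dplyr::mutate(expected_fate = unname(.CLASS_FATE[.data$class]),
                  expected_stage = unname(.CLASS_STAGE[.data$class])) |>
    dplyr::select("locus_id", "class", "part", "copy", "assembly", "contig",
                  "start", "end", "motif", "repeats", "expected_fate",
                  "expected_stage") |>
    dplyr::arrange(.data$locus_id, .data$assembly, .data$part, .data$copy)
  # whole-assembly validation: mining assembly A must recover exactly the
  # planted records (guards against chance repeats at chunk junctions)
  planted_a <- truth[truth$assembly == labels[1L], , drop = FALSE]
  mined <- find_ssrs(assemblies[[1L]])
  key_mined <- paste(mined$contig, mined$start, mined$end)
  key_truth <- paste(planted_a$contig, planted_a$start, planted_a$end)
  if (nrow(mined) != nrow(planted_a) || !setequal(key_mined, key_truth)) {
    return(NULL)
  }
  list(assemblies = assemblies, truth = truth)
}
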