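test_that("amplicon motif scan matches up to cyclic rotation only", {
  env <- asNamespace("polyssr")
  pad1 <- withr::with_seed(1, env$clean_dna(40))
  pad2 <- withr::with_seed(2, env$clean_dna(40))
  wrap <- function(core) paste0(pad1, core, pad2)
  expect_equal(scan_amplicon_ssr(wrap("TATATATATATA"), "AT"), 12L)
  expect_true(is.na(scan_amplicon_ssr(wrap("AGAGAGAGAGAG"), "AT")))
  expect_true(is.na(scan_amplicon_ssr(wrap(strrep("AT", 4)), "AT",
                                      min_units = 5L)))
  # reverse complement deliberately does not match (orientation is fixed)
  expect_true(is.na(scan_amplicon_ssr(wrap(strrep("GT", 8)), "AC")))
  # longest qualifying run wins
  two <- paste0(pad1, strrep("AT", 5), pad2, strrep("TA", 9), pad1)
  expect_equal(scan_amplicon_ssr(two, "AT"), 18L)
})

# minimal in-memory evidence builder
mk_eval <- function(lens, runs, counts = NULL, labels = NULL, motif = "AT",
                    mode = "any_differ") {
  if (is.null(labels)) labels <- paste0("a", seq_along(lens))
  markers <- tibble::tibble(marker_id = "m1", motif = motif, unit_len = 2L)
  env <- asNamespace("polyssr")
  rows <- list()
  for (i in seq_along(lens)) {
    n_amp <- if (is.null(counts)) 1L else counts[i]
    for (k in seq_len(n_amp)) {
      pad_total <- lens[i] - runs[i]
      pad1 <- withr::with_seed(100 + i, env$clean_dna(pad_total %/% 2))
      pad2 <- withr::with_seed(200 + i,
                               env$clean_dna(pad_total - pad_total %/% 2))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker_id = "m1", assembly = labels[i], contig = "c",
        start = 1L, end = lens[i], length = lens[i],
        orientation = "fwd_first",
        seq = paste0(pad1, strrep(motif, runs[i] %/% 2L), pad2))
    }
  }
  evaluate_markers(markers, dplyr::bind_rows(rows), labels,
                   polymorphism_mode = mode)
}

test_that("verdicts follow the fixed criterion order", {
  # lengths 150/154, runs 30/34: flanks equal, runs differ -> selected
  expect_equal(mk_eval(c(150L, 154L), c(30L, 34L))$verdict, "selected")
  # identical alleles -> monomorphic
  expect_equal(mk_eval(c(150L, 150L), c(30L, 30L))$verdict, "monomorphic")
  # length difference not attributable to the SSR -> flank_variation
  expect_equal(mk_eval(c(150L, 154L), c(30L, 30L))$verdict, "flank_variation")
  # two amplicons in one assembly -> multi_site
  expect_equal(mk_eval(c(150L, 154L), c(30L, 34L),
                       counts = c(1L, 2L))$verdict, "multi_site")
  # missing assembly -> absent
  ev <- mk_eval(c(150L, 154L), c(30L, 34L), counts = c(1L, 0L))
  expect_equal(ev$verdict, "absent")
})

test_that("polymorphism modes differ only for partial ties", {
  lens <- c(150L, 154L, 150L)
  runs <- c(30L, 34L, 30L)  # two assemblies share an allele
  expect_equal(mk_eval(lens, runs)$verdict, "selected")
  expect_equal(mk_eval(lens, runs, mode = "all_distinct")$verdict,
               "monomorphic")
})

test_that("verdicts partition the tested markers and reports are written", {
  fx <- tiny_fixture(seed = 7L)
  res <- suppressMessages(run_pipeline(fx$assemblies))
  ev <- res$evaluations
  expect_equal(nrow(ev), sum(res$complexity$status == "pass"))
  expect_true(all(ev$verdict %in% c("selected", "multi_site", "absent",
                                    "motif_mismatch", "flank_variation",
                                    "monomorphic")))
  # repeat number re-derivation is integral for selected markers
  tab <- marker_amplicon_table(res$markers, res$amplicons, ev)
  expect_true(all(tab$repeats_inferred == round(tab$repeats_inferred)))
  d <- withr::local_tempdir()
  final <- write_final_report(ev, res$markers, res$amplicons, d)
  expect_true(file.exists(file.path(d, "final_markers.tsv")))
  audit <- readr::read_tsv(file.path(d, "marker_audit.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(audit), nrow(ev))
  expect_equal(nrow(final), sum(ev$verdict == "selected"))
})

test_that("zero selected markers still yields a complete audit", {
  env <- asNamespace("polyssr")
  # two assemblies with one identical (monomorphic) locus
  fx <- generate_assemblies(
    n_assemblies = 2L, counts = c(monomorphic = 2L), seed = 3L)
  res <- suppressMessages(run_pipeline(fx$assemblies))
  expect_equal(sum(res$evaluations$verdict == "selected"), 0L)
  d <- withr::local_tempdir()
  final <- write_final_report(res$evaluations, res$markers, res$amplicons, d)
  expect_equal(nrow(final), 0L)
  audit <- readr::read_tsv(file.path(d, "marker_audit.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(audit), nrow(res$evaluations))
})
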