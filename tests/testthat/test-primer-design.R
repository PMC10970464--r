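make_region <- function(seed, motif = "AT", reps = 12L, flank = 200L) {
  env <- asNamespace("polyssr")
  withr::with_seed(seed, {
    list(seq = paste0(env$clean_dna(flank), strrep(motif, reps),
                      env$clean_dna(flank)),
         ssr_start = flank + 1L,
         ssr_end = flank + reps * nchar(motif))
  })
}

test_that("returned pairs satisfy every hard constraint", {
  cfg <- design_config(n_results = 3L)
  found <- 0L
  for (seed in 1:8) {
    r <- make_region(seed)
    p <- design_primers(r$seq, r$ssr_start, r$ssr_end, cfg)
    found <- found + nrow(p)
    for (i in seq_len(nrow(p))) {
      for (pr in c(p$fwd[i], p$rev[i])) {
        expect_gte(nchar(pr), cfg$size_min)
        expect_lte(nchar(pr), cfg$size_max)
        expect_lte(max_mono_run(pr), cfg$max_mono_run)
        expect_gte(gc_content(pr), cfg$gc_min)
        expect_lte(gc_content(pr), cfg$gc_max)
        expect_gte(melting_temp(pr), cfg$tm_min)
        expect_lte(melting_temp(pr), cfg$tm_max)
      }
      # primers flank the SSR: forward strictly upstream, reverse window
      # strictly downstream, product contains the whole SSR
      expect_lte(p$fwd_end[i], r$ssr_start - 1L)
      expect_gte(p$rev_start[i], r$ssr_end + 1L)
      expect_equal(p$product_len[i], p$rev_end[i] - p$fwd_start[i] + 1L)
      expect_gte(p$product_len[i], cfg$product_min)
      expect_lte(p$product_len[i], cfg$product_max)
      # reported stats equal the scalar functions on the primer sequences
      expect_equal(p$tm_f[i], melting_temp(p$fwd[i]))
      expect_equal(p$tm_r[i], melting_temp(p$rev[i]))
      expect_equal(p$gc_f[i], gc_content(p$fwd[i]))
      # the reverse primer is the reverse complement of its plus-strand window
      expect_equal(p$rev[i],
                   revcomp(substr(r$seq, p$rev_start[i], p$rev_end[i])))
    }
  }
  expect_gt(found, 0L)
})

test_that("design agrees with the exhaustive pair-search oracle", {
  cfg <- design_config()
  checked <- 0L
  for (seed in 11:14) {
    r <- make_region(seed)
    got <- design_primers(r$seq, r$ssr_start, r$ssr_end, cfg)
    want <- oracle_design(r$seq, r$ssr_start, r$ssr_end, cfg)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      checked <- checked + 1L
      expect_equal(got$fwd, want$fwd)
      expect_equal(got$rev, want$rev)
      expect_equal(got$product_len, want$product)
      expect_equal(got$penalty, want$pen, tolerance = 1e-9)
    }
  }
  expect_gt(checked, 0L)
})

test_that("infeasible flanks yield an empty result, not an error", {
  # all-AT flanks: GC content is 0 everywhere, below the 40% floor
  r <- list(seq = paste0(strrep("TTAA", 50), strrep("AT", 12),
                         strrep("TTAA", 50)),
            ssr_start = 201L, ssr_end = 224L)
  p <- design_primers(r$seq, r$ssr_start, r$ssr_end)
  expect_equal(nrow(p), 0L)
})

test_that("design is deterministic", {
  r <- make_region(21)
  p1 <- design_primers(r$seq, r$ssr_start, r$ssr_end)
  p2 <- design_primers(r$seq, r$ssr_start, r$ssr_end)
  expect_identical(p1, p2)
})

test_that("windows containing N are never used", {
  r <- make_region(31)
  # sprinkle Ns into the upstream flank
  s <- strsplit(r$seq, "")[[1]]
  s[c(30L, 90L, 150L)] <- "N"
  poisoned <- paste(s, collapse = "")
  p <- design_primers(poisoned, r$ssr_start, r$ssr_end)
  for (i in seq_len(nrow(p))) {
    expect_false(grepl("N", p$fwd[i]))
    expect_false(grepl("N", p$rev[i]))
  }
  # and the result still agrees with the oracle, which skips N windows
  want <- oracle_design(poisoned, r$ssr_start, r$ssr_end, design_config())
  if (is.null(want)) {
    expect_equal(nrow(p), 0L)
  } else {
    expect_equal(p$fwd, want$fwd)
    expect_equal(p$rev, want$rev)
  }
})

test_that("optional self-complementarity screen filters hairpin-prone primers", {
  env <- asNamespace("polyssr")
  expect_equal(env$longest_selfcomp("AAGCTT"), 6L)
  expect_lte(env$longest_selfcomp("AAAAAAAAAA"), 2L)
  r <- make_region(41)
  p0 <- design_primers(r$seq, r$ssr_start, r$ssr_end,
                       design_config(self_screen = TRUE))
  for (i in seq_len(nrow(p0))) {
    expect_lte(env$longest_selfcomp(p0$fwd[i]), 8L)
    expect_lte(env$longest_selfcomp(p0$rev[i]), 8L)
  }
})
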