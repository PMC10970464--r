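FWD <- "ACGATCCGTTAGCAGGTACC"
REV <- "TGGCAACGTTGATCCGAGTT"  # as written 5'->3' on the product's right end

planted_assembly <- function(seed, gap = 160L, both_orientations = FALSE) {
  env <- asNamespace("polyssr")
  withr::with_seed(seed, {
    s <- paste0(env$clean_dna(300), FWD, env$clean_dna(gap), revcomp(REV),
                env$clean_dna(300))
    if (both_orientations) {
      s <- paste0(s, REV, env$clean_dna(gap), revcomp(FWD),
                  env$clean_dna(200))
    }
    new_assembly(c(c1 = s), paste0("pl", seed))
  })
}

test_that("site finding reports exact full-length matches on both strands", {
  a <- planted_assembly(1)
  sf <- find_primer_sites(a, FWD)
  expect_equal(nrow(sf), 1L)
  expect_equal(sf$strand, "+")
  expect_equal(sf$start, 301L)
  sr <- find_primer_sites(a, REV)  # only the reverse complement is present
  expect_equal(nrow(sr), 1L)
  expect_equal(sr$strand, "-")
  # N in the subject never matches
  b <- new_assembly(c(c1 = sub("ACGATCCGTT", "ACGATNCGTT",
                               a$seq[["c1"]])), "n")
  expect_equal(nrow(find_primer_sites(b, FWD)), 0L)
})

test_that("site finding equals the naive sliding-window oracle", {
  for (seed in 1:5) {
    a <- planted_assembly(seed, both_orientations = TRUE)
    for (p in c(FWD, REV)) {
      expect_equal(find_primer_sites(a, p), oracle_sites(a, p))
    }
  }
})

test_that("amplification pairs inward-facing sites within the span limit", {
  a <- planted_assembly(2, gap = 160L)
  amps <- amplify(a, FWD, REV)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$length, 20L + 160L + 20L)
  expect_equal(amps$orientation, "fwd_first")
  expect_equal(substr(amps$seq, 1, 20), FWD)
  # span beyond the limit never amplifies
  far <- planted_assembly(3, gap = 1580L)
  expect_equal(nrow(amplify(far, FWD, REV)), 0L)
  # but a raised limit recovers it
  expect_equal(nrow(amplify(far, FWD, REV, max_amplicon = 2000L)), 1L)
})

test_that("two forward sites in range of one reverse site give two products", {
  env <- asNamespace("polyssr")
  a <- withr::with_seed(4, new_assembly(c(c1 = paste0(
    env$clean_dna(100), FWD, env$clean_dna(60), FWD, env$clean_dna(100),
    revcomp(REV), env$clean_dna(100))), "t"))
  amps <- amplify(a, FWD, REV)
  expect_equal(nrow(amps), 2L)
  expect_equal(length(unique(amps$end)), 1L)
})

test_that("same-strand co-occurrence and overlapping sites never amplify", {
  env <- asNamespace("polyssr")
  # both primers as-is on the plus strand: no inward-facing pair
  a <- withr::with_seed(5, new_assembly(c(c1 = paste0(
    env$clean_dna(100), FWD, env$clean_dna(100), REV,
    env$clean_dna(100))), "t"))
  expect_equal(nrow(amplify(a, FWD, REV)), 0L)
  # overlapping sites (reverse site begins inside the forward site)
  core <- paste0(FWD, "ACGTTGCCAGT")
  b <- new_assembly(c(c1 = paste0(strrep("G", 50), core, strrep("G", 50))),
                    "t")
  rv <- revcomp(substr(core, 10, 29))  # its site overlaps the forward site
  expect_equal(nrow(amplify(b, FWD, rv)), 0L)
})

test_that("amplification equals the brute-force pairing oracle", {
  for (seed in 6:9) {
    a <- planted_assembly(seed, both_orientations = TRUE)
    got <- amplify(a, FWD, REV)[, c("contig", "start", "end")]
    want <- oracle_amplify(a, FWD, REV)
    expect_equal(got, want)
  }
})

test_that("reverse-complementing the assembly preserves amplicon lengths", {
  for (seed in 10:12) {
    a <- planted_assembly(seed, both_orientations = TRUE)
    flipped <- new_assembly(vapply(a$seq, revcomp, character(1)), "flip")
    l1 <- sort(amplify(a, FWD, REV)$length)
    l2 <- sort(amplify(flipped, FWD, REV)$length)
    expect_equal(l2, l1)
  }
})

test_that("external hit tables drive the same pairing logic", {
  a <- planted_assembly(13, both_orientations = TRUE)
  to_hits <- function(primer, role) {
    s <- find_primer_sites(a, primer)
    tibble::tibble(query = role, contig = s$contig, identity = 100,
                   aln_len = nchar(primer), start = s$start, end = s$end,
                   strand = s$strand)
  }
  hits <- rbind(to_hits(FWD, "fwd"), to_hits(REV, "rev"))
  # a partial-length, lower-identity decoy hit must be ignored
  hits <- rbind(hits, tibble::tibble(query = "fwd", contig = "c1",
                                     identity = 95, aln_len = 20L,
                                     start = 10L, end = 29L, strand = "+"),
                tibble::tibble(query = "rev", contig = "c1", identity = 100,
                               aln_len = 12L, start = 40L, end = 51L,
                               strand = "-"))
  got <- pair_external_hits(hits, FWD, REV)
  want <- amplify(a, FWD, REV)
  expect_equal(got[, c("contig", "start", "end", "length")],
               want[, c("contig", "start", "end", "length")])
})
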