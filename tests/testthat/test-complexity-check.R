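test_that("relaxed detector flags partial units beyond the strict run", {
  # a complete-unit miner reports ATGATG (6 bp) in ATGATGAT; the relaxed
  # detector flags all 8 bp, a 2 bp extension within the 5 bp allowance
  seg <- paste0("GCCAGTCGCA", "ATGATGAT", "CGTCCAGGCA")
  fl <- find_low_complexity(seg, allowance_config(lc_min_len = 8))
  expect_equal(nrow(fl), 1L)
  expect_equal(c(fl$start, fl$end), c(11L, 18L))
  mined <- find_ssrs(new_assembly(c(c1 = seg), "t"), ssr_thresholds("3" = 2))
  expect_equal(c(mined$start, mined$end), c(11L, 16L))
  expect_equal(fl$end - mined$end, 2L)  # within the default 5 bp overhang
})

test_that("planted runs are flagged at default thresholds and merged", {
  env <- asNamespace("polyssr")
  seg <- withr::with_seed(5, paste0(env$clean_dna(60), strrep("AT", 15),
                                    env$clean_dna(50), strrep("A", 14),
                                    env$clean_dna(60)))
  fl <- find_low_complexity(seg)
  expect_equal(nrow(fl), 2L)
  expect_equal(fl$start[1], 61L)
  expect_equal(fl$start[2], 141L)
  # a short stretch below lc_min_len is not flagged
  expect_equal(nrow(find_low_complexity(paste0(env$clean_dna(40),
                                               strrep("AT", 5),
                                               env$clean_dna(40)))), 0L)
})

complexity_marker_fixture <- function(extra = NULL, gap_after_extra = 10L) {
  env <- asNamespace("polyssr")
  withr::with_seed(12, {
    fl_l <- env$clean_dna(120)
    fl_r <- env$clean_dna(120)
    mid <- if (is.null(extra)) "" else
      paste0(extra, env$clean_dna(gap_after_extra))
    region <- paste0(fl_l, mid, strrep("AT", 12), fl_r)
    ssr_start <- 120L + nchar(mid) + 1L
    a <- new_assembly(c(c1 = region), "t")
    markers <- tibble::tibble(
      marker_id = "c1:ssr", contig = "c1",
      ssr_start = ssr_start, ssr_end = ssr_start + 23L,
      fwd_start = 1L, fwd_end = 20L,
      rev_start = nchar(region) - 19L, rev_end = nchar(region),
      product_start = 1L, product_end = nchar(region))
    list(assembly = a, markers = markers)
  })
}

test_that("markers pass when only the SSR (plus allowance) is low complexity", {
  fx <- complexity_marker_fixture()
  expect_message(v <- check_markers(fx$markers, fx$assembly), "skipped")
  expect_equal(v$status, "pass")
})

test_that("extra low-complexity stretches beyond the allowance fail", {
  fx <- complexity_marker_fixture(extra = strrep("A", 20))
  v <- suppressMessages(check_markers(fx$markers, fx$assembly))
  expect_equal(v$status, "extra_low_complexity")
  # a run hugging the SSR within the overhang is tolerated: grow the SSR
  # stretch by 4 bp of trailing partial unit -> still pass
  env <- asNamespace("polyssr")
  region <- withr::with_seed(30, paste0(env$clean_dna(120), strrep("AT", 12),
                                        "ATA", env$clean_dna(117)))
  a <- new_assembly(c(c1 = region), "t")
  m <- tibble::tibble(marker_id = "m", contig = "c1",
                      ssr_start = 121L, ssr_end = 144L,
                      fwd_start = 1L, fwd_end = 20L,
                      rev_start = nchar(region) - 19L,
                      rev_end = nchar(region),
                      product_start = 1L, product_end = nchar(region))
  expect_equal(suppressMessages(check_markers(m, a))$status, "pass")
})

test_that("mask overlap is reported when masks are supplied", {
  fx <- complexity_marker_fixture()
  masks <- tibble::tibble(contig = "c1", start = 50L, end = 60L)
  v <- check_markers(fx$markers, fx$assembly, masks = masks)
  expect_equal(v$status, "masked_overlap")
  # non-overlapping mask: pass
  far <- tibble::tibble(contig = "c1", start = 5000L, end = 5100L)
  expect_equal(check_markers(fx$markers, fx$assembly, masks = far)$status,
               "pass")
  bad <- tibble::tibble(contig = "nope", start = 1L, end = 10L)
  expect_error(check_markers(fx$markers, fx$assembly, masks = bad),
               "absent")
})

test_that("verdict is invariant under flipping the whole fixture", {
  fx <- complexity_marker_fixture(extra = strrep("A", 20))
  flipped <- new_assembly(c(c1 = revcomp(fx$assembly$seq[["c1"]])), "t")
  n <- nchar(fx$assembly$seq[["c1"]])
  m <- fx$markers
  m2 <- tibble::tibble(
    marker_id = m$marker_id, contig = "c1",
    ssr_start = n - m$ssr_end + 1L, ssr_end = n - m$ssr_start + 1L,
    fwd_start = n - m$rev_end + 1L, fwd_end = n - m$rev_start + 1L,
    rev_start = n - m$fwd_end + 1L, rev_end = n - m$fwd_start + 1L,
    product_start = 1L, product_end = n)
  v1 <- suppressMessages(check_markers(m, fx$assembly))
  v2 <- suppressMessages(check_markers(m2, flipped))
  expect_equal(v2$status, v1$status)
})

test_that("mask readers handle BED and RepeatMasker-style tables", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t99\t200\tx\t0\t+", "c2\t0\t10\ty\t0\t-"), bed)
  mb <- read_mask_bed(bed)
  expect_equal(mb$start, c(100L, 1L))  # 0-based half-open -> 1-based incl.
  expect_equal(mb$end, c(200L, 10L))

  out <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query",
    "score   div. del. ins.  sequence  begin end",
    "",
    "  463   1.3  0.6  1.7  c1        100   250 (100) + AT_rich Simple_repeat",
    "  239   2.0  0.0  0.0  c2         12    40  (10) C  A-rich Low_complexity"
  ), out)
  mo <- read_mask_rmout(out)
  expect_equal(mo$contig, c("c1", "c2"))
  expect_equal(mo$start, c(100L, 12L))
  expect_equal(mo$end, c(250L, 40L))
})
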