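mk_blocks <- function(q_start, q_end, s_start, s_end, identity = 90,
                      query = "sc1", subject = "chr1") {
  data.frame(query_id = query, q_start = q_start, q_end = q_end,
             subject_id = subject, s_start = s_start, s_end = s_end,
             identity = identity,
             aligned_length = abs(q_end - q_start) + 1L,
             stringsAsFactors = FALSE)
}

test_that("orientation classification follows coordinate direction", {
  fwd <- classifyOrientation(mk_blocks(100, 200, 1000, 1100))
  expect_identical(as.character(fwd$orientation), "forward")
  rev <- classifyOrientation(mk_blocks(100, 200, 1100, 1000))
  expect_identical(as.character(rev$orientation), "reverse")
  # involution: flipping subject coordinates flips the class
  flip <- mk_blocks(100, 200, 1100, 1000)
  tmp <- flip$s_start; flip$s_start <- flip$s_end; flip$s_end <- tmp
  expect_identical(as.character(classifyOrientation(flip)$orientation),
                   "forward")
  expect_error(classifyOrientation(mk_blocks(100, 100, 1, 50)),
               "zero-length")
})

test_that("planted inversions are classified reverse, and only those", {
  for (seed in c(2, 12)) {
    syn <- simSynteny(n_blocks = 60, n_inversions = 4, seed = seed)
    ob <- classifyOrientation(syn$blocks)
    expect_setequal(ob$block_id[ob$orientation == "reverse"], syn$truth)
    none <- simSynteny(n_blocks = 30, n_inversions = 0, seed = seed)
    expect_true(all(classifyOrientation(none$blocks)$orientation ==
                      "forward"))
  }
})

test_that("dot-plot filter applies inclusive length and span thresholds", {
  chrom <- c(chr1 = 1e6)
  # scaffold span 2000 bp < 0.25% of 1 Mb (2500): excluded
  small <- mk_blocks(1, 2000, 1, 2000)
  small$aligned_length <- 2000L
  expect_identical(nrow(dotplotFilter(small, chrom, min_aln = 2000)), 0L)
  # span exactly at 2500 and block exactly at min_aln: kept (inclusive)
  at <- mk_blocks(1, 2500, 1, 2500)
  at$aligned_length <- 2500L
  expect_identical(nrow(dotplotFilter(at, chrom, min_aln = 2500)), 1L)
  # block below 3 kb dropped regardless of scaffold span
  b <- rbind(mk_blocks(1, 2999, 1, 2999), mk_blocks(3000, 9000, 3000, 9000))
  b$aligned_length <- c(2999L, 6001L)
  kept <- dotplotFilter(b, chrom)
  expect_identical(kept$aligned_length, 6001L)
  expect_error(dotplotFilter(at, c(chrX = 100)), "unknown chromosome")
})

test_that("dot-plot span predicate is recomputed after subsetting", {
  chrom <- c(chr1 = 1e6)
  # two 3 kb blocks of one scaffold: joint span 6000 passes 0.25% only
  # jointly; dropping one must drop the survivor too on re-filtering
  b <- rbind(mk_blocks(1, 3000, 1, 3000),
             mk_blocks(5000, 6999, 5000, 6999))
  b$aligned_length <- c(3000L, 2000L)
  first <- dotplotFilter(b, chrom, min_aln = 1500, min_fraction = 0.004)
  expect_identical(nrow(first), 2L)  # span 5000 >= 4000
  second <- dotplotFilter(first[1, ], chrom, min_aln = 1500,
                          min_fraction = 0.004)
  expect_identical(nrow(second), 0L)  # span 3000 < 4000 recomputed
})

test_that("aligned-portion denominator is available behind the flag", {
  chrom <- c(chr1 = 1e7)
  b <- rbind(mk_blocks(1, 4000, 1, 4000, query = "scA"),
             mk_blocks(1, 3500, 5000, 8499, query = "scB"))
  b$aligned_length <- c(4000L, 3500L)
  # chromosome denominator: spans 4000 and 3500 both < 0.25% of 10 Mb
  expect_identical(nrow(dotplotFilter(b, chrom)), 0L)
  # aligned denominator: 7500 aligned bp in total, both pass 0.25%
  expect_identical(nrow(dotplotFilter(b, chrom, fraction_of = "aligned")),
                   2L)
})

test_that("chord filter thresholds are strict", {
  sc_len <- c(scA = 500000, scB = 600000)
  b <- rbind(mk_blocks(1, 20000, 1, 20000, query = "scA"),
             mk_blocks(1, 10001, 1, 10001, query = "scB"),
             mk_blocks(1, 10000, 30000, 39999, query = "scB"))
  b$aligned_length <- c(20000L, 10001L, 10000L)
  kept <- chordFilter(b, sc_len)
  expect_identical(nrow(kept), 1L)     # scA excluded at exactly 500 kb
  expect_identical(kept$query_id, "scB")
  expect_identical(kept$aligned_length, 10001L)  # 10 kb exactly excluded
  expect_error(chordFilter(b, c(scA = 1)), "unknown scaffold")
})

test_that("chromosome summary weights identity and merges coverage", {
  b <- rbind(mk_blocks(1, 100, 1, 100, identity = 80),
             mk_blocks(1, 300, 200, 499, identity = 90))
  b$aligned_length <- c(100L, 300L)
  cs <- chromosomeSummary(b, c(chr1 = 1000))
  expect_equal(cs$per_chromosome$weighted_identity, 87.5)
  expect_identical(cs$per_chromosome$covered_bp, 400L)

  # overlapping subject intervals are merged before counting
  ov <- rbind(mk_blocks(1, 100, 1, 100), mk_blocks(1, 100, 51, 150))
  cs2 <- chromosomeSummary(ov, c(chr1 = 1000))
  expect_identical(cs2$per_chromosome$covered_bp, 150L)
  expect_equal(cs2$overall_coverage, 0.15)

  # chromosome without blocks reports zero coverage
  cs3 <- chromosomeSummary(b, c(chr1 = 1000, chr2 = 500))
  expect_equal(cs3$per_chromosome$coverage_fraction[2], 0)
  expect_equal(cs3$overall_coverage, 400 / 1500)
})

test_that("union coverage never exceeds chromosome length; identity is convex", {
  set.seed(20)
  for (i in 1:10) {
    syn <- simSynteny(n_blocks = 40, n_inversions = 5, seed = i)
    cs <- chromosomeSummary(syn$blocks, syn$chrom_lengths)
    expect_lte(cs$per_chromosome$covered_bp, syn$chrom_lengths[["chr1"]])
    expect_lte(cs$overall_coverage, 1)
    wi <- cs$per_chromosome$weighted_identity
    expect_gte(wi, min(syn$blocks$identity))
    expect_lte(wi, max(syn$blocks$identity))
    # merged union equals the base-marking oracle
    expect_identical(cs$per_chromosome$covered_bp,
                     oracle_union(pmin(syn$blocks$s_start, syn$blocks$s_end),
                                  pmax(syn$blocks$s_start, syn$blocks$s_end)))
  }
})

test_that("coords tables read with the show-coords column layout", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(1, 5000, 1, 5000, 5000, 5000, 88.5, "chr1", "sc1",
                     sep = "\t"),
               paste(9000, 6001, 1, 3000, 3000, 3000, 90.0, "chr1", "sc2",
                     sep = "\t")), f)
  blocks <- readCoords(f)
  expect_identical(blocks$query_id, c("sc1", "sc2"))
  expect_identical(blocks$s_start, c(1L, 9000L))
  expect_identical(blocks$aligned_length, c(5000L, 3000L))
  ob <- classifyOrientation(blocks)
  expect_identical(as.character(ob$orientation), c("forward", "reverse"))
})
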