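# fixture: one genome with a 3-fold collapse and a 2-copy retained repeat
corefind_fixture <- function(seed = 11, depth = 20) {
  gt <- simulate_genome(
    30000,
    list(planted_feature("collapsed", 1000, 3, 1),
         planted_feature("repeated_non_collapsed", 1000, 2, 2)),
    gc = 0.5, seed = seed)
  rd <- simulate_reads(gt, depth = depth, read_length = 100, seed = seed + 100)
  list(gt = gt, reads = rd,
       tracks = coverage_from_reads(rd, gt$assembly, seed = seed + 200))
}

test_that("the mapping emulator matches brute-force coverage on a unique genome", {
  gt <- simulate_genome(5000, list(), seed = 41)
  rd <- simulate_reads(gt, depth = 15, read_length = 100, seed = 42)
  tr <- coverage_from_reads(rd, gt$assembly, seed = 43)
  expect_equal(tr$unmapped, 0)
  # on a repeat-free genome every read maps uniquely to its origin
  stack <- oracle_depth_counts(
    tibble::tibble(start = rd$src_start - 1, end = rd$src_start + 99), 5000)
  t <- tr$tracks$seq1
  expect_equal(t$r0, stack)
  expect_equal(t$r1, stack)
  expect_equal(t$r2, stack)
})

test_that("mode ordering and coverage-mass conservation hold at every base", {
  fx <- corefind_fixture()
  t <- fx$tracks$tracks$seq1
  expect_true(all(t$r0 <= t$r1))
  expect_true(all(t$r1 <= t$r2))
  mapped <- nrow(fx$reads) - fx$tracks$unmapped
  expect_equal(sum(t$r1), mapped * 100)
})

test_that("a 2-copy exact repeat zeroes r0 and doubles r2 in copy interiors", {
  gt <- simulate_genome(20000, planted_feature("repeated_non_collapsed", 1000, 2, 2),
                        seed = 51)
  rd <- simulate_reads(gt, 20, 100, seed = 52)
  tr <- coverage_from_reads(rd, gt$assembly, seed = 53)
  t <- tr$tracks$seq1
  iv <- gt$features$coords[[1]]
  interior <- (iv$start[1] + 150):(iv$end[1] - 150)
  expect_equal(max(t$r0[interior]), 0)
  expect_gt(median(t$r1[interior]), 10)
  expect_gt(median(t$r2[interior]), 1.5 * median(t$r2))
})

test_that("an unmappable read is counted as unmapped", {
  gt <- simulate_genome(5000, list(), seed = 61)
  tr <- coverage_from_reads(c(strrep("ACGT", 25)), gt$assembly, seed = 1)
  expect_equal(tr$unmapped, 1)
})

test_that("classification recovers planted features with high overlap and copy number", {
  for (seed in c(11, 23, 37)) {
    fx <- corefind_fixture(seed)
    regions <- classify_regions(fx$tracks)
    rec <- planted_recall(regions, fx$gt, min_overlap = 0.9, fuzz = 100)
    expect_equal(rec$recall_percent, 100)
    expect_true(all(rec$per_copy$overlap >= 0.9))
    cn <- rec$copy_number
    expect_lt(abs(cn$copy_number[cn$kind == "collapsed"] - 3) / 3, 0.2)
    expect_lt(abs(cn$copy_number[cn$kind == "repeated_non_collapsed"] - 2) / 2, 0.2)
  }
})

test_that("flat coverage yields no regions and merging is idempotent", {
  gt <- simulate_genome(10000, list(), seed = 71)
  rd <- simulate_reads(gt, 20, 100, seed = 72)
  tr <- coverage_from_reads(rd, gt$assembly, seed = 73)
  expect_equal(nrow(classify_regions(tr)), 0)
  # idempotence: regions re-merged with the same gap are unchanged
  fx <- corefind_fixture()
  regions <- classify_regions(fx$tracks)
  remerged <- wgdkit:::merge_close(dplyr::select(regions, start, end), 100)
  expect_equal(nrow(remerged), nrow(regions))
})

test_that("copy number is the ratio of region r2 median to the overall r2 median", {
  tracks <- wgdkit:::new_coverage_tracks(list(
    s1 = list(r0 = rep(10L, 1000), r1 = rep(10L, 1000),
              r2 = c(rep(10L, 800), rep(52L, 200)))))
  expect_equal(estimate_copy_number(tibble::tibble(seq_id = "s1", start = 0, end = 500),
                                    tracks), 1.0)
  expect_equal(estimate_copy_number(tibble::tibble(seq_id = "s1", start = 800, end = 1000),
                                    tracks), 5.2)
  expect_error(estimate_copy_number(tibble::tibble(seq_id = "s1", start = 800, end = 2000),
                                    tracks), "bounds")
})

test_that("five-column table round trip preserves the track set", {
  fx <- corefind_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_table(fx$tracks, f)
  back <- coverage_from_table(f)
  expect_equal(back$tracks$seq1, fx$tracks$tracks$seq1)
  # mode-ordering violations are rejected
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq_id\tpos\tr0\tr1\tr2", "s1\t1\t5\t3\t8"), bad)
  expect_error(coverage_from_table(bad), "ordering")
})

test_that("BED round trip preserves region coordinates and kinds", {
  fx <- corefind_fixture()
  regions <- classify_regions(fx$tracks)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions, f)
  back <- read_regions_bed(f)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
  expect_equal(back$kind, regions$kind)
  # empty set: header-only file
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions[0, ], f2)
  expect_equal(nrow(read_regions_bed(f2)), 0)
  expect_true(startsWith(readLines(f2)[1], "#"))
})
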