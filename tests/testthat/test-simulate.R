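test_that("genome simulation keeps exact length bookkeeping and manifests", {
  # no features: assembly equals truth
  gt0 <- simulate_genome(30000, list(), gc = 0.5, seed = 1)
  expect_identical(gt0$assembly, gt0$truth)
  expect_equal(nrow(gt0$features), 0)

  # a 3-fold collapse assembled once adds 2 x 1000 bases to the truth
  gt <- simulate_genome(30000, planted_feature("collapsed", 1000, 3, 1),
                        gc = 0.5, seed = 7)
  expect_equal(nchar(gt$truth[[1]]), 32000)
  expect_equal(nchar(gt$assembly[[1]]), 30000)

  # retained 2-copy repeat: two identical intervals in the assembly
  gt2 <- simulate_genome(30000, planted_feature("repeated_non_collapsed", 1000, 2, 2),
                         gc = 0.5, seed = 7)
  iv <- gt2$features$coords[[1]]
  s <- gt2$assembly[[1]]
  expect_equal(nrow(iv), 2)
  expect_identical(substr(s, iv$start[1] + 1, iv$end[1]),
                   substr(s, iv$start[2] + 1, iv$end[2]))
  # and the copies equal the recorded unit sequence
  expect_identical(substr(s, iv$start[1] + 1, iv$end[1]), gt2$features$unit_seq[1])
})

test_that("genome simulation rejects oversized features and is deterministic", {
  expect_error(simulate_genome(5000, planted_feature("collapsed", 1000, 3, 1)),
               "10x")
  a <- simulate_genome(20000, planted_feature("collapsed", 800, 4, 1), seed = 3)
  b <- simulate_genome(20000, planted_feature("collapsed", 800, 4, 1), seed = 3)
  expect_identical(a$assembly, b$assembly)
  expect_identical(a$truth, b$truth)
  expect_identical(a$features$coords, b$features$coords)
})

test_that("read simulation honours the count formula, exactness and seeding", {
  gt <- simulate_genome(10000, list(), seed = 2)
  rd <- simulate_reads(gt, depth = 40, read_length = 100, seed = 5)
  expect_equal(nrow(rd), 4000)
  # error-free reads are exact substrings of the truth (up to strand)
  some <- rd[1:50, ]
  fwd <- ifelse(some$strand == "+", some$seq, wgdkit:::revcomp(some$seq))
  expect_true(all(fwd == substring(gt$truth[some$src_seq], some$src_start,
                                   some$src_start + 99)))
  # byte-identical FASTQ for a fixed seed
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(simulate_reads(gt, 5, 100, seed = 9), f1)
  write_fastq(simulate_reads(gt, 5, 100, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_reads(gt, 5, 100, error_rate = 0.7), "error_rate")
  expect_error(simulate_reads(gt, 5, read_length = 20000), "shorter")
})

test_that("codon-pair simulation hits the target Ks and respects contracts", {
  # identical pairs at target 0
  p0 <- simulate_codon_pairs(3, 0, n_codons = 50, seed = 1)
  expect_identical(p0$seq_a, p0$seq_b)
  # mean estimated Ks within 10% of the 0.30 target over 200 pairs
  pp <- simulate_codon_pairs(200, 0.30, n_codons = 300, seed = 11)
  est <- ng86_table(pp)
  expect_lt(abs(mean(est$Ks, na.rm = TRUE) - 0.30), 0.03)
  expect_true(all(est$Ka == 0, na.rm = TRUE))  # only synonymous changes planted
  # different seeds: different sequences, same summary within tolerance
  p1 <- simulate_codon_pairs(100, 0.2, 120, seed = 1)
  p2 <- simulate_codon_pairs(100, 0.2, 120, seed = 2)
  expect_false(identical(p1$seq_a, p2$seq_a))
  expect_lt(abs(mean(ng86_table(p1)$Ks) - mean(ng86_table(p2)$Ks)), 0.02)
  expect_error(simulate_codon_pairs(5, 50, 100), "saturation")
})

test_that("planted synteny reproduces its own depth fractions and block contracts", {
  ps <- plant_synteny(1e6, list(list(multiplicity = 3, fraction = 0.2, median_ks = 0.3)),
                      seed = 4)
  expect_equal(ps$depth_truth$fraction[ps$depth_truth$depth == 3], 0.2, tolerance = 0.01)
  # anchors per planted block never fall below min_block
  per_block <- dplyr::count(ps$anchors, block_id_truth)
  expect_true(all(per_block$n >= ps$params$min_block))
  # empty event list
  ps0 <- plant_synteny(1e5, list(), seed = 1)
  expect_equal(nrow(ps0$anchors), 0)
  expect_equal(ps0$depth_truth, tibble::tibble(depth = 0L, fraction = 1))
  expect_error(plant_synteny(1e5, list(list(multiplicity = 2, fraction = 0.8, median_ks = 1),
                                       list(multiplicity = 1, fraction = 0.5, median_ks = 1))),
               "sum")
})

test_that("modal distance simulation equals path sums at zero noise", {
  tr <- event_tree(tibble::tibble(
    node = c("root", "A", "B"), parent = c(NA, "root", "root"),
    type = c("wgd", "tip", "tip"), length = c(NA, 0.12, 0.08)))
  obs <- simulate_modal_distances(tr, noise_sd = 0, seed = 1)
  expect_equal(obs$observed[obs$kind == "ortholog"], 0.20)
  expect_setequal(obs$observed[obs$kind == "paralog"], c(0.24, 0.16))
})
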