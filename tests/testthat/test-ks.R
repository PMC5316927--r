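test_that("NG86 matches hand-derived values on the worked single-difference case", {
  res <- ng86_pairwise("TTTGGTGGTGGTGGT", "TTCGGTGGTGGTGGT")
  expect_equal(res$S, 13 / 3)
  expect_equal(res$ps, 3 / 13)
  expect_equal(res$Ks, -0.75 * log(1 - 4 / 3 * 3 / 13))
  expect_equal(res$Ka, 0)
  # identical sequences
  res0 <- ng86_pairwise("ATGGCT", "ATGGCT")
  expect_equal(res0$Ks, 0)
  expect_equal(res0$Ka, 0)
})

test_that("NG86 agrees with the brute-force enumeration oracle on random pairs", {
  set.seed(404)
  for (i in 1:150) {
    pr <- random_codon_pair(n_codons = 25, n_mut = sample(0:8, 1))
    got <- ng86_pairwise(pr$a, pr$b)
    want <- oracle_ng86(pr$a, pr$b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$ps, want$ps, tolerance = 1e-12)
    expect_equal(got$Ks, want$Ks, tolerance = 1e-12)
    expect_equal(got$Ka, want$Ka, tolerance = 1e-12)
  }
})

test_that("NG86 is symmetric, conserves sites, and errors on saturation", {
  set.seed(77)
  for (i in 1:20) {
    pr <- random_codon_pair(30, sample(0:6, 1))
    ab <- ng86_pairwise(pr$a, pr$b)
    ba <- ng86_pairwise(pr$b, pr$a)
    expect_equal(ab$Ks, ba$Ks)
    expect_equal(ab$Ka, ba$Ka)
    expect_equal(ab$S + ab$N, 3 * ab$n_codons)
  }
  # saturation boundary: TTT vs TTC has ps = 3/13... single codon: ps = 1
  expect_error(ng86_pairwise("TTT", "TTC"), "saturation")
  # gap codons are excluded; an all-gap alignment is empty
  expect_error(ng86_pairwise("---", "ATG"), "countable")
  mix <- ng86_pairwise("ATG---GGT", "ATGGCTGGT")
  expect_equal(mix$n_codons, 2)
})

test_that("Jukes-Cantor correction is strictly increasing in p", {
  p <- seq(0, 0.74, by = 0.002)
  d <- vapply(p, wgdkit:::jc_correct, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("chaining matches the exhaustive-search optimum on small anchor sets", {
  set.seed(99)
  for (trial in 1:60) {
    n <- sample(4:12, 1)
    anc <- random_anchor_set(n, span = 5000)
    max_gap <- sample(c(500, 2000, 10000), 1)
    dp_f <- wgdkit:::best_chain_dp(anc, max_gap, 0.01, reverse = FALSE)
    dp_r <- wgdkit:::best_chain_dp(anc, max_gap, 0.01, reverse = TRUE)
    expect_equal(max(dp_f$score, dp_r$score),
                 oracle_best_chain_score(anc, max_gap, 0.01))
  }
})

test_that("chaining splits runs at large gaps and enforces the block minimum", {
  collinear <- function(n, offset_a, offset_b) tibble::tibble(
    gene_a = paste0("a", seq_len(n)), chr_a = "A",
    start_a = offset_a + (seq_len(n) - 1) * 500L,
    end_a = offset_a + (seq_len(n) - 1) * 500L + 200L,
    gene_b = paste0("b", seq_len(n)), chr_b = "B",
    start_b = offset_b + (seq_len(n) - 1) * 500L,
    end_b = offset_b + (seq_len(n) - 1) * 500L + 200L,
    score = 100)
  one <- chain_anchors(collinear(10, 0, 0), max_gap = 1000, min_block = 5)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_anchors, 10)
  two <- chain_anchors(dplyr::bind_rows(collinear(6, 0, 0), collinear(6, 50000, 50000)),
                       max_gap = 1000, min_block = 5)
  expect_equal(nrow(two), 2)
  none <- chain_anchors(collinear(4, 0, 0), max_gap = 1000, min_block = 5)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(chain_anchors(collinear(0, 0, 0))), 0)
})

test_that("reverse-orientation runs are chained and labelled", {
  n <- 8
  anc <- tibble::tibble(
    gene_a = paste0("a", 1:n), chr_a = "A",
    start_a = (1:n - 1) * 500L, end_a = (1:n - 1) * 500L + 200L,
    gene_b = paste0("b", 1:n), chr_b = "B",
    start_b = (n:1 - 1) * 500L, end_b = (n:1 - 1) * 500L + 200L,
    score = 100)
  bl <- chain_anchors(anc, max_gap = 1000, min_block = 5)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$orientation, "reverse")
})

test_that("top-anchor retention keeps one best hit per query per target chromosome", {
  anc <- tibble::tibble(gene_a = c("g1", "g1", "g1", "g2"),
                        chr_b = c("c1", "c1", "c2", "c1"),
                        score = c(90, 95, 40, 70))
  kept <- filter_top_anchors(anc)
  expect_equal(nrow(kept), 3)
  expect_equal(kept$score[kept$gene_a == "g1" & kept$chr_b == "c1"], 95)
})

test_that("block medians follow the even/odd median convention and drop saturated anchors", {
  expect_equal(block_median_ks(c(0.1, 0.3, 0.2)), 0.2)
  expect_equal(block_median_ks(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  expect_equal(block_median_ks(c(0.1, NA, 0.3)), 0.2)
  expect_warning(res <- block_median_ks(c(NA_real_, NA_real_)), "saturated")
  expect_true(is.na(res))
})

test_that("Ks histograms are proportion-normalised with half-open bins", {
  h <- ks_histogram(0.25, bin_width = 0.1)
  expect_equal(h$proportion[h$bin_start == 0.2], 1)
  set.seed(5)
  hu <- ks_histogram(runif(20000), bin_width = 0.1)
  expect_true(all(abs(hu$proportion[1:10] - 0.1) < 0.01))
  expect_equal(sum(hu$proportion), 1, tolerance = 1e-9)
  expect_error(ks_histogram(c(0.1, -0.2)), "negative")
  # boundary values land in the right-hand bin
  hb <- ks_histogram(c(0.1, 0.1, 0.05), bin_width = 0.1)
  expect_equal(hb$n, c(1, 2))
})

test_that("modal peak finding recovers unimodal and bimodal mixtures", {
  set.seed(42)
  uni <- ks_histogram(pmax(0, rnorm(10000, 0.3, 0.05)), bin_width = 0.01)
  pk <- find_modal_peaks(uni, min_prominence = 0.01)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$ks_mode - 0.30), 0.01)

  bi <- ks_histogram(pmax(0, c(rnorm(5000, 0.12, 0.03), rnorm(5000, 0.68, 0.06))),
                     bin_width = 0.01)
  pk2 <- find_modal_peaks(bi, min_prominence = 0.002)
  expect_equal(nrow(pk2), 2)
  expect_lt(abs(pk2$ks_mode[1] - 0.12), 0.01)
  expect_lt(abs(pk2$ks_mode[2] - 0.68), 0.01)

  flat <- ks_histogram(seq(0.005, 0.995, by = 0.01), bin_width = 0.01)
  expect_equal(nrow(find_modal_peaks(flat, min_prominence = 0.002)), 0)
  expect_error(find_modal_peaks(uni, smooth_window = 4), "odd")
})

test_that("planted two-event genomes give a two-peak block-median histogram", {
  ps <- plant_synteny(4e6, list(list(multiplicity = 2, fraction = 0.25, median_ks = 0.30),
                                list(multiplicity = 1, fraction = 0.35, median_ks = 0.74)),
                      seed = 8)
  bl <- chain_anchors(ps$anchors, max_gap = 20000, gap_penalty = 0.001,
                      min_block = ps$params$min_block)
  pk <- find_modal_peaks(ks_histogram(bl$median_ks))
  expect_gte(nrow(pk), 2)
  expect_lt(min(abs(pk$ks_mode - 0.30)), 0.01)
  expect_lt(min(abs(pk$ks_mode - 0.74)), 0.01)
})
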