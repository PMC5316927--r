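# fixture: markers cut verbatim from a synthetic assembly
marker_fixture <- function(seed = 2, n = 5, amp_len = 300, primer_len = 20) {
  gt <- simulate_genome(20000, gc = 0.45, seed = seed)
  s <- gt$assembly[[1]]
  starts <- seq(1000, 16000, length.out = n)
  assays <- lapply(seq_len(n), function(i) {
    a0 <- round(starts[i])
    amp <- substr(s, a0, a0 + amp_len - 1)
    marker_assay(paste0("mk", i),
                 fwd = substr(amp, 1, primer_len),
                 rev = wgdkit:::revcomp(substr(amp, amp_len - primer_len + 1, amp_len)),
                 platform = "other", amplicon = amp)
  })
  list(assembly = gt$assembly, assays = assays,
       truth = tibble::tibble(name = paste0("mk", seq_len(n)),
                              start = round(starts) - 1, end = round(starts) - 1 + amp_len))
}

test_that("verbatim markers are placed back at their source with distance zero", {
  fx <- marker_fixture()
  for (i in seq_along(fx$assays)) {
    cand <- insilico_pcr(fx$assays[[i]], fx$assembly)
    placed <- place_marker(cand)
    expect_equal(placed$status, "placed")
    expect_equal(placed$method, "epcr")
    expect_equal(placed$dist, 0L)
    expect_equal(placed$start, fx$truth$start[i])
    expect_equal(placed$end, fx$truth$end[i])
  }
})

test_that("primer mismatches are tolerated up to the caps and counted", {
  fx <- marker_fixture(seed = 5, n = 1)
  assay <- fx$assays[[1]]
  # introduce two substitutions into the forward primer
  fwd <- assay$fwd
  for (p in c(5, 12)) {
    substr(fwd, p, p) <- setdiff(c("A", "C", "G", "T"), substr(fwd, p, p))[1]
  }
  mut <- marker_assay("mut", fwd, assay$rev, platform = "other")
  cand <- insilico_pcr(mut, fx$assembly)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$mm, 2L)
  expect_equal(cand$dist, 2L)
  # a third mismatch exceeds the cap
  substr(fwd, 18, 18) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 18, 18))[1]
  mut3 <- marker_assay("mut3", fwd, assay$rev, platform = "other")
  expect_equal(nrow(insilico_pcr(mut3, fx$assembly)), 0)
})

test_that("amplicon size ranges screen candidates by platform", {
  fx <- marker_fixture(seed = 7, n = 1, amp_len = 1200)
  assay <- fx$assays[[1]]
  # 1200 bp product is inside the generic range but outside fluidigm's
  expect_equal(nrow(insilico_pcr(assay, fx$assembly)), 1)
  flu <- marker_assay(assay$name, assay$fwd, assay$rev, platform = "fluidigm")
  expect_equal(nrow(insilico_pcr(flu, fx$assembly)), 0)
})

test_that("two equally distant sites are ambiguous; fallback hits rescue placement", {
  # duplicate the amplicon region so ePCR finds two perfect sites
  gt <- simulate_genome(20000, planted_feature("repeated_non_collapsed", 600, 2, 2),
                        seed = 9)
  iv <- gt$features$coords[[1]]
  s <- gt$assembly[[1]]
  amp <- substr(s, iv$start[1] + 1, iv$start[1] + 400)
  assay <- marker_assay("dup", substr(amp, 1, 20), wgdkit:::revcomp(substr(amp, 381, 400)),
                        platform = "other", amplicon = amp)
  cand <- insilico_pcr(assay, gt$assembly)
  expect_gte(nrow(cand), 2)
  expect_equal(place_marker(cand)$status, "ambiguous")
  # no candidates at all, one clean similarity hit -> sequence_hit placement
  uniq_amp <- substr(s, 15000, 15399)
  fb <- amplicon_hits(uniq_amp, gt$assembly)
  placed <- place_marker(cand[0, ], fb[1, ])
  expect_equal(placed$status, "placed")
  expect_equal(placed$method, "sequence_hit")
  expect_equal(placed$start, 14999)
  # nothing anywhere -> unplaced
  expect_equal(place_marker(cand[0, ], NULL)$status, "unplaced")
})

test_that("every marker ends placed, ambiguous or unplaced (decision totality)", {
  fx <- marker_fixture(seed = 13, n = 4)
  outcomes <- vapply(fx$assays, function(a)
    place_marker(insilico_pcr(a, fx$assembly))$status, character(1))
  expect_true(all(outcomes %in% c("placed", "ambiguous", "unplaced")))
  expect_equal(length(outcomes), 4)
})
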