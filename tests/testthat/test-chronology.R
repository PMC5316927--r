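two_tip_tree <- function() event_tree(tibble::tibble(
  node = c("root", "A", "B"), parent = c(NA, "root", "root"),
  type = c("wgd", "tip", "tip")))

test_that("the design matrix encodes ortholog and paralog path sums", {
  tr <- two_tip_tree()
  obs <- tibble::tibble(kind = c("ortholog", "paralog", "paralog"),
                        tip_a = c("A", "A", "B"), tip_b = c("B", "root", "root"),
                        observed = c(0.2, 0.24, 0.16))
  sys <- build_system(tr, obs)
  expect_equal(unname(sys$A), rbind(c(1, 1), c(2, 0), c(0, 2)))
  expect_equal(sys$d, c(0.2, 0.24, 0.16))
  # duplicate observations become duplicate rows, unweighted
  sys2 <- build_system(tr, dplyr::bind_rows(obs, obs[1, ]))
  expect_equal(nrow(sys2$A), 4)
  expect_equal(sys2$A[4, ], sys2$A[1, ])
  # an event not ancestral to the tip is a topology error
  bad <- tibble::tibble(kind = "paralog", tip_a = "A", tip_b = "B", observed = 0.1)
  expect_error(build_system(tr, bad), "ancestral")
})

test_that("a five-genome legume-style topology with three duplications has 11 unknowns", {
  # WGD-rooted tree: root duplication -> basal speciation; one lineage
  # carries a triplication, another a nested duplication
  nodes <- tibble::tibble(
    node   = c("root", "base", "wgt", "Lang", "s2", "s3", "Mtru", "Ljap",
               "s4", "Pvul", "wgd_g", "Gmax"),
    parent = c(NA, "root", "base", "wgt", "base", "s2", "s3", "s3",
               "s2", "s4", "s4", "wgd_g"),
    type   = c("wgd", "speciation", "wgt", "tip", "speciation", "speciation",
               "tip", "tip", "speciation", "tip", "wgd", "tip"))
  tr <- event_tree(nodes)
  obs <- simulate_modal_distances(
    event_tree(dplyr::mutate(nodes, length = ifelse(is.na(parent), NA, 0.1))),
    noise_sd = 0, seed = 1)
  sys <- build_system(tr, obs)
  expect_equal(ncol(sys$A), 11)
  expect_true(all(sys$A %in% 0:2))
})

test_that("exact solve recovers the two-branch system with zero residual", {
  tr <- two_tip_tree()
  obs <- tibble::tibble(kind = c("ortholog", "paralog", "paralog"),
                        tip_a = c("A", "A", "B"), tip_b = c("B", "root", "root"),
                        observed = c(0.2, 0.24, 0.16))
  sys <- build_system(tr, obs)
  fit <- solve_branch_lengths(sys$A, sys$d)
  expect_equal(unname(fit$lengths), c(0.12, 0.08))
  expect_lt(fit$residual, 1e-12)
  # dropping a row of a minimally determined system is under-determination
  expect_error(solve_branch_lengths(sys$A[1:1, , drop = FALSE], sys$d[1]),
               "under-determined")
})

test_that("noiseless round trips recover branch lengths and ages on random trees", {
  for (seed in 1:10) {
    tr <- random_event_tree(5, 2, seed = seed)
    obs <- simulate_modal_distances(tr, noise_sd = 0, seed = seed)
    fit <- solve_chronology(tr, obs, calibration_age = 58)
    truth <- assign_dates(tr, calibration_age = 58)
    expect_lt(max(abs(tidy(fit)$length - tidy(truth)$length), na.rm = TRUE), 1e-9)
    expect_lt(max(abs(tidy(fit)$age - tidy(truth)$age)), 1e-9)
    expect_lt(glance(fit)$residual, 1e-9)
  }
})

test_that("ages are calibrated at the root, zero at tips, monotone to the tips", {
  tr <- random_event_tree(6, 3, seed = 14)
  chron <- assign_dates(tr, calibration_age = 58)
  td <- tidy(chron)
  expect_equal(td$age[is.na(td$parent)], 58)
  expect_true(all(td$age[td$type == "tip"] == 0))
  # every child is younger than (or equal to) its parent
  kids <- td[!is.na(td$parent), ]
  expect_true(all(kids$age <= td$age[match(kids$parent, td$node)] + 1e-9))
})

test_that("a lineage with WGT and root paralog peaks dates the WGT by proportional scaling", {
  tr <- event_tree(tibble::tibble(
    node = c("root", "wgt", "L"), parent = c(NA, "root", "wgt"),
    type = c("wgd", "wgt", "tip")))
  obs <- tibble::tibble(kind = c("paralog", "paralog"), tip_a = c("L", "L"),
                        tip_b = c("wgt", "root"), observed = c(0.30, 0.74))
  chron <- solve_chronology(tr, obs, calibration_age = 58)
  td <- tidy(chron)
  expect_equal(td$age[td$node == "wgt"], 58 * 0.15 / 0.37, tolerance = 1e-9)
  # branch rates are Ks per My along each branch
  expect_equal(td$rate[td$node == "L"], 0.15 / (58 * 0.15 / 0.37), tolerance = 1e-9)
})

test_that("noisy observations still date nodes to within a few My", {
  errs <- vapply(1:50, function(rep) {
    tr <- random_event_tree(5, 2, seed = 500 + rep)
    obs <- simulate_modal_distances(tr, noise_sd = 0.01, seed = 900 + rep)
    fit <- suppressWarnings(solve_chronology(tr, obs, calibration_age = 58))
    truth <- assign_dates(tr, calibration_age = 58)
    td_f <- tidy(fit); td_t <- tidy(truth)
    internal <- td_t$type != "tip" & !is.na(td_t$parent)
    max(abs(td_f$age[internal] - td_t$age[internal]))
  }, numeric(1))
  expect_lt(median(errs), 3)
})

test_that("negative solved lengths are clipped with a warning", {
  A <- rbind(c(1, 1), c(2, 0), c(0, 2))
  d <- c(0.1, 0.4, -0.05)
  expect_warning(fit <- solve_branch_lengths(A, d), "clipped")
  expect_true(all(fit$lengths >= 0))
  expect_true(fit$clipped)
})

test_that("event-tree validation enforces rooting, reachability and unary duplications", {
  expect_error(event_tree(tibble::tibble(node = c("a", "b"), parent = c(NA, NA),
                                         type = c("tip", "tip"))), "root")
  expect_error(event_tree(tibble::tibble(node = c("r", "x", "y"),
                                         parent = c(NA, "r", "zz"),
                                         type = c("speciation", "tip", "tip"))),
               "unknown parent")
  # a non-root duplication node with two children is rejected
  expect_error(event_tree(tibble::tibble(
    node = c("r", "d", "x", "y"), parent = c(NA, "r", "d", "d"),
    type = c("speciation", "wgd", "tip", "tip"))), "unary")
})

test_that("the bracketed newick dialect round-trips event trees", {
  tr <- random_event_tree(4, 2, seed = 3)
  tr2 <- read_event_newick(write_event_newick(tr))
  a <- dplyr::arrange(tr$nodes, node)
  b <- dplyr::arrange(tr2$nodes, node)
  expect_equal(a$parent, b$parent)
  expect_equal(a$type, b$type)
  expect_equal(a$length, b$length, tolerance = 1e-5)
})
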