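# End-to-end demonstration pipeline on synthetic data with known truth.

#' Default demo configuration
#'
#' All stage parameters of [run_demo()] with their defaults. Unknown
#' keys passed to `run_demo()` are rejected.
#'
#' @return named list of parameters.
#' @export
demo_config <- function() {
  list(
    seed = 1,
    genome_length = 30000,
    depth = 20,
    kmer_depth = 40,
    read_length = 100,
    gc = 0.5,
    collapsed_copies = 3,
    repeat_copies = 2,
    unit_length = 1000,
    kmer_k = 17,
    n_codon_pairs = 100,
    codon_target_ks = 0.30,
    n_codons = 300,
    synteny_ref_length = 2000000,
    synteny_events = list(list(multiplicity = 3, fraction = 0.2, median_ks = 0.30),
                          list(multiplicity = 1, fraction = 0.3, median_ks = 0.74)),
    chronology_tips = 5,
    chronology_dups = 2,
    calibration_age = 58
  )
}

#' Run the full synthetic-data demonstration pipeline
#'
#' Generates a genome with planted collapsed and retained repeats plus
#' uniform reads, then runs every analysis stage -- k-mer genome-size
#' estimation, collapsed/repeat classification, Ka/Ks estimation on
#' simulated codon pairs, synteny chaining with block-median Ks
#' histogram and modal peaks, synteny depth profiling, chronology
#' solving on a random event tree -- and compares each recovered
#' quantity to the generator's manifest. Artifacts (FASTA/FASTQ/TSV/
#' JSON/BED) and a `report.tsv` are written to `out_dir`. All
#' randomness derives from `config$seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param config list of parameters; see [demo_config()]. Partial lists
#'   are merged over the defaults; unknown keys are an error.
#' @return the check report tibble, invisibly. An attribute `"passed"`
#'   records whether every check passed.
#' @export
run_demo <- function(out_dir, config = list()) {
  defaults <- demo_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checks <- list()
  note <- function(stage, check, value, truth, tol) {
    checks[[length(checks) + 1]] <<- tibble(
      stage = stage, check = check, value = value, truth = truth,
      tolerance = tol, pass = abs(value - truth) <= tol)
  }

  # --- genome + reads ---
  gt <- simulate_genome(
    cfg$genome_length,
    features = list(
      planted_feature("collapsed", unit_length = cfg$unit_length,
                      copies_in_truth = cfg$collapsed_copies, copies_in_assembly = 1),
      planted_feature("repeated_non_collapsed", unit_length = cfg$unit_length,
                      copies_in_truth = cfg$repeat_copies)),
    gc = cfg$gc, seed = cfg$seed)
  reads <- simulate_reads(gt, depth = cfg$depth, read_length = cfg$read_length,
                          seed = cfg$seed + 1)
  write_fasta(gt, file.path(out_dir, "assembly.fasta"), "assembly")
  write_fasta(gt, file.path(out_dir, "truth.fasta"), "truth")
  write_fastq(reads, file.path(out_dir, "reads.fastq"))

  # --- k-mer genome size (deeper read set: the peak-depth equation
  # needs enough coverage that +-1 multiplicity is a small relative error) ---
  kmer_reads <- simulate_reads(gt, depth = cfg$kmer_depth,
                               read_length = cfg$read_length, seed = cfg$seed + 7)
  kh <- count_kmers(kmer_reads, k = cfg$kmer_k)
  gsize <- estimate_genome_size(kh)
  truth_size <- sum(nchar(gt$truth))
  note("kmer", "genome_size_bp", gsize, truth_size, 0.05 * truth_size)
  readr::write_tsv(kh$spectrum, file.path(out_dir, "kmer_spectrum.tsv"), progress = FALSE)

  # --- collapsed/repeat classification ---
  tracks <- coverage_from_reads(reads, gt$assembly, seed = cfg$seed + 2)
  regions <- classify_regions(tracks)
  write_coverage_table(tracks, file.path(out_dir, "coverage.tsv"))
  write_bed(regions, file.path(out_dir, "regions.bed"))
  recall <- planted_recall(regions, gt, fuzz = cfg$read_length)
  note("corefind", "recall_percent", recall$recall_percent, 100, 0)
  cn_coll <- recall$copy_number$copy_number[recall$copy_number$kind == "collapsed"]
  note("corefind", "collapsed_copy_number", cn_coll, cfg$collapsed_copies,
       0.2 * cfg$collapsed_copies)

  # --- Ka/Ks on simulated codon pairs ---
  pairs <- simulate_codon_pairs(cfg$n_codon_pairs, cfg$codon_target_ks,
                                n_codons = cfg$n_codons, seed = cfg$seed + 3)
  est <- ng86_table(pairs)
  note("ks", "mean_ks", mean(est$Ks, na.rm = TRUE), cfg$codon_target_ks,
       0.1 * cfg$codon_target_ks)
  readr::write_tsv(select(est, -"seq_a", -"seq_b"),
                   file.path(out_dir, "codon_pairs_ks.tsv"), progress = FALSE)

  # --- synteny: chaining, medians, histogram, peaks, depth ---
  ps <- plant_synteny(cfg$synteny_ref_length, cfg$synteny_events, seed = cfg$seed + 4)
  blocks <- chain_anchors(ps$anchors, max_gap = 20000, gap_penalty = 0.001,
                          min_block = ps$params$min_block)
  write_blocks(blocks, file.path(out_dir, "blocks.tsv"))
  hist <- ks_histogram(blocks$median_ks)
  peaks <- find_modal_peaks(hist)
  readr::write_tsv(peaks, file.path(out_dir, "ks_peaks.tsv"), progress = FALSE)
  truth_modes <- sort(vapply(cfg$synteny_events, `[[`, numeric(1), "median_ks"))
  found <- vapply(truth_modes, function(m)
    if (nrow(peaks)) min(abs(peaks$ks_mode - m)) else Inf, numeric(1))
  note("ks", "peak_recovery_max_err", max(found), 0, attr(hist, "bin_width"))

  dp <- depth_profile(blocks, c(ref = cfg$synteny_ref_length))
  readr::write_tsv(depth_table(list(demo = dp)), file.path(out_dir, "synteny_depth.tsv"),
                   progress = FALSE)
  for (i in seq_len(nrow(ps$depth_truth))) {
    d <- ps$depth_truth$depth[i]
    got <- dp$summary$fraction[dp$summary$depth == d]
    note("synteny_depth", paste0("fraction_depth_", d),
         if (length(got)) got else 0, ps$depth_truth$fraction[i], 0.01)
  }

  # --- chronology on a random event tree ---
  tr <- random_event_tree(cfg$chronology_tips, cfg$chronology_dups, seed = cfg$seed + 5)
  obs <- simulate_modal_distances(tr, noise_sd = 0, seed = cfg$seed + 6)
  write_observations(obs, file.path(out_dir, "modal_observations.tsv"))
  chron <- solve_chronology(tr, obs, calibration_age = cfg$calibration_age)
  true_chron <- assign_dates(tr, calibration_age = cfg$calibration_age)
  err <- max(abs(tidy(chron)$age - tidy(true_chron)$age))
  note("chronology", "max_node_age_error_my", err, 0, 1e-6)
  readr::write_tsv(tidy(chron), file.path(out_dir, "chronology.tsv"), progress = FALSE)

  # --- assembly metrics on the synthetic scaffold set ---
  stats <- nstats(c(nchar(gt$assembly), cfg$unit_length * 2, cfg$unit_length * 5))
  readr::write_tsv(stats, file.path(out_dir, "nstats.tsv"), progress = FALSE)

  report <- bind_rows(checks)
  readr::write_tsv(report, file.path(out_dir, "report.tsv"), progress = FALSE)
  cfg_out <- cfg
  cfg_out$synteny_events <- NULL
  jsonlite::write_json(cfg_out, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(report, "passed") <- all(report$pass)
  invisible(report)
}

#' Recall of planted repeat features against classified regions
#'
#' For each planted feature copy, checks whether a region of the
#' expected kind (`coll` for collapsed features, `rnc` for retained
#' repeats) overlaps at least `min_overlap` of the planted interval.
#'
#' @param regions region tibble from [classify_regions()].
#' @param gt a `genome_truth`.
#' @param min_overlap minimum planted-interval overlap fraction.
#' @param fuzz boundary fuzz allowance in bases, trimmed from each end
#'   of the planted interval before measuring overlap. Coverage-based
#'   flags cannot resolve repeat boundaries more finely than the read
#'   length (a read partially overlapping a repeat still maps uniquely),
#'   so pass the read length here.
#' @return list with `per_copy` tibble, `recall_percent`, and
#'   `copy_number` (mean estimate per feature kind).
#' @export
planted_recall <- function(regions, gt, min_overlap = 0.9, fuzz = 0) {
  rows <- list()
  for (i in seq_len(nrow(gt$features))) {
    f <- gt$features[i, ]
    want <- if (f$kind == "collapsed") "coll" else "rnc"
    iv <- f$coords[[1]]
    iv$start <- iv$start + fuzz
    iv$end <- pmax(iv$end - fuzz, iv$start + 1)
    for (j in seq_len(nrow(iv))) {
      hits <- filter(regions, .data$kind == want)
      ov <- if (nrow(hits)) pmax(0, pmin(hits$end, iv$end[j]) - pmax(hits$start, iv$start[j]))
      else 0
      best <- if (length(ov)) max(ov) / (iv$end[j] - iv$start[j]) else 0
      cn <- if (length(ov) && max(ov) > 0) hits$copy_number[which.max(ov)] else NA_real_
      rows[[length(rows) + 1]] <- tibble(
        feature_id = f$feature_id, kind = f$kind, copy = j,
        overlap = best, detected = best >= min_overlap, copy_number = cn)
    }
  }
  per_copy <- bind_rows(rows)
  cn <- per_copy |> group_by(.data$kind) |>
    summarise(copy_number = mean(.data$copy_number, na.rm = TRUE), .groups = "drop")
  list(per_copy = per_copy,
       recall_percent = 100 * mean(per_copy$detected),
       copy_number = cn)
}
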