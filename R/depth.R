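# Per-base synteny coverage depth: at each reference position, the
# number of synteny-block footprints covering it. The distribution of
# depth over the genome is ploidy evidence -- e.g. a whole-genome
# triplication in the query lineage shows up as a large fraction of the
# reference at depth three.

#' Per-base synteny coverage depth profile
#'
#' Depth at each base is the number of covering block intervals,
#' computed by interval stacking (run-length encoded). Optionally
#' excludes trivial self-match blocks (identical coordinates on both
#' genomes of a self-comparison) before profiling.
#'
#' @param blocks tibble of block footprints on the reference: columns
#'   `chr_a`, `start_a`, `end_a` (0-based half-open) as produced by
#'   [chain_anchors()], or `seq_id`, `start`, `end`.
#' @param genome_lengths named vector of reference sequence lengths.
#' @param exclude_self drop main-diagonal self matches (requires
#'   `chr_b`, `start_b`, `end_b` columns).
#' @return a `depth_profile`: list with `runs` (tibble `seq_id`, `start`,
#'   `end`, `depth`) and `summary` (tibble `depth`, `fraction`; fractions
#'   over the total genome length, summing to one).
#' @export
depth_profile <- function(blocks, genome_lengths, exclude_self = FALSE) {
  blocks <- as_tibble(blocks)
  if ("seq_id" %in% names(blocks)) {
    blocks <- dplyr::rename(blocks, chr_a = "seq_id", start_a = "start", end_a = "end")
  }
  if (exclude_self) {
    stopifnot(all(c("chr_b", "start_b", "end_b") %in% names(blocks)))
    blocks <- filter(blocks, !(.data$chr_a == .data$chr_b &
                                 .data$start_a == .data$start_b &
                                 .data$end_a == .data$end_b))
  }
  if (nrow(blocks) > 0) {
    if (!all(blocks$chr_a %in% names(genome_lengths)))
      abort("block on a sequence absent from genome_lengths")
    too_far <- blocks$end_a > genome_lengths[blocks$chr_a] | blocks$start_a < 0
    if (any(too_far)) abort("block interval beyond sequence bounds")
  }
  runs <- list()
  tally <- list()
  for (s in names(genome_lengths)) {
    bs <- filter(blocks, .data$chr_a == s)
    cov <- IRanges::coverage(IRanges::IRanges(start = bs$start_a + 1, end = bs$end_a),
                             width = genome_lengths[[s]])
    rl <- S4Vectors::runLength(cov)
    rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl)
    runs[[s]] <- tibble(seq_id = s, start = ends - rl, end = ends, depth = as.integer(rv))
    tally[[s]] <- tibble(depth = as.integer(rv), bases = as.numeric(rl))
  }
  summary <- bind_rows(tally) |>
    group_by(.data$depth) |>
    summarise(bases = sum(.data$bases), .groups = "drop") |>
    mutate(fraction = .data$bases / sum(.data$bases)) |>
    select("depth", "fraction") |>
    arrange(.data$depth)
  structure(list(runs = bind_rows(runs), summary = summary,
                 total_length = sum(genome_lengths)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile>", format(x$total_length, big.mark = " "), "bp\n")
  print(x$summary)
  invisible(x)
}

#' Cross-comparison synteny depth table
#'
#' One row per depth level, one column per genome comparison; cells are
#' the percentage of the reference genome at that depth, to one
#' decimal. Depth levels run contiguously from 0 to the maximum seen in
#' any profile.
#'
#' @param profiles named list of [depth_profile()] results, names
#'   labelling the (reference, query) comparisons.
#' @return tibble with `depth` and one percentage column per profile, in
#'   input order.
#' @export
depth_table <- function(profiles) {
  if (length(profiles) == 0) abort("at least one profile required")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("comparison", seq_along(profiles))
  dmax <- max(vapply(profiles, function(p) max(p$summary$depth), numeric(1)))
  out <- tibble(depth = 0:dmax)
  for (nm in names(profiles)) {
    s <- profiles[[nm]]$summary
    v <- numeric(dmax + 1)
    v[s$depth + 1] <- s$fraction
    out[[nm]] <- round_half_up(100 * v, 1)
  }
  out
}
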