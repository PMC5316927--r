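# Assembly, genetic-map and genome-window summary statistics.

#' Assembly length statistics (N50 and friends)
#'
#' N50 is defined by the cumulative-half convention on lengths sorted
#' descending: `n50_length` is the length of the sequence at which the
#' cumulative length first reaches half the total, and `n50_count` its
#' 1-based rank. The mean is rounded half-up to the nearest base.
#'
#' @param x numeric vector of sequence lengths, a named character vector
#'   of sequences, or a tibble with a `length` column.
#' @return one-row tibble: `total`, `count`, `mean`, `max`, `min`,
#'   `n50_count`, `n50_length`.
#' @export
nstats <- function(x) {
  lens <- if (is.data.frame(x)) x$length
  else if (is.character(x)) nchar(x)
  else as.numeric(x)
  if (length(lens) == 0) abort("empty sequence set")
  stopifnot(all(lens > 0))
  lens <- sort(lens, decreasing = TRUE)
  cum <- cumsum(lens)
  i50 <- which(cum >= sum(lens) / 2)[1]
  tibble(total = sum(lens), count = length(lens),
         mean = round_half_up(mean(lens)), max = max(lens), min = min(lens),
         n50_count = i50, n50_length = lens[i50])
}

#' Filter sequences by length and masked fraction
#'
#' Drops sequences shorter than `min_length` or with a masked fraction
#' (repetitive, simple-repeat or unknown N bases) of at least
#' `max_masked`.
#'
#' @param seqs tibble with `name`, `length`, `masked_fraction` columns.
#' @param min_length minimum length kept (bases).
#' @param max_masked masked-fraction threshold (inclusive).
#' @return list with `kept` (tibble) and `dropped` (tibble with a
#'   `reason` column: `"length"` or `"mask"`; length takes precedence
#'   when both apply).
#' @export
filter_sequences <- function(seqs, min_length = 200, max_masked = 0.5) {
  seqs <- as_tibble(seqs)
  stopifnot(all(c("name", "length", "masked_fraction") %in% names(seqs)),
            all(seqs$masked_fraction >= 0 & seqs$masked_fraction <= 1))
  reason <- dplyr::case_when(
    seqs$length < min_length ~ "length",
    seqs$masked_fraction >= max_masked ~ "mask",
    TRUE ~ NA_character_
  )
  list(kept = seqs[is.na(reason), ],
       dropped = mutate(seqs[!is.na(reason), ], reason = reason[!is.na(reason)]))
}

#' Percentage of a part over a whole, rounded half-up
#'
#' @param part,whole counts or base totals; `whole` must be positive.
#' @param decimals decimals in the result.
#' @return `100 * part / whole` rounded half-up.
#' @export
ratio_percent <- function(part, whole, decimals = 1) {
  if (any(whole <= 0)) abort("whole must be > 0")
  round_half_up(100 * part / whole, decimals)
}

#' Genetic map summary statistics
#'
#' Total map length is the sum over linkage groups of the maximum
#' marker position; each group with `k` loci contributes `k - 1`
#' marker intervals (a single-locus group contributes none, with a
#' warning), and the mean interval is the total length divided by the
#' total interval count, to two decimals.
#'
#' @param map tibble with `marker`, `group`, `pos_cm` columns.
#' @return one-row tibble: `total_cm`, `groups`, `loci`, `mean_interval`.
#' @export
map_summary <- function(map) {
  map <- as_tibble(map)
  stopifnot(all(c("marker", "group", "pos_cm") %in% names(map)),
            all(map$pos_cm >= 0))
  per <- map |>
    group_by(.data$group) |>
    summarise(span = max(.data$pos_cm), loci = n(), .groups = "drop")
  if (any(per$loci == 1))
    warn(sprintf("%d linkage group(s) with a single locus contribute no intervals",
                 sum(per$loci == 1)))
  intervals <- sum(per$loci - 1)
  tibble(total_cm = sum(per$span), groups = nrow(per), loci = sum(per$loci),
         mean_interval = round_half_up(sum(per$span) / intervals, 2))
}

#' Per-window feature density and GC tracks
#'
#' Non-overlapping windows tiled from position 0. For positioned
#' features (a tibble of `chrom`, `pos`), each window reports its raw
#' count and the density per Mb, scaled by the window's true width (so
#' a partial final window is not under-weighted). For sequences, each
#' window reports GC% over its non-N bases.
#'
#' @param x a tibble with `chrom` and `pos` (1-based) columns, or
#'   sequences (named character / `DNAStringSet` / FASTA path).
#' @param window window size in bases (default 100 kb).
#' @param seq_lengths named lengths, required for feature input.
#' @return tibble with `chrom`, `win_start`, `win_end` (0-based
#'   half-open) and either `count` + `per_mb`, or `gc_percent`.
#' @export
window_tracks <- function(x, window = 100000, seq_lengths = NULL) {
  stopifnot(window > 0)
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "pos") %in% names(x)))
    if (is.null(seq_lengths)) abort("seq_lengths is required for feature input")
    out <- list()
    for (s in names(seq_lengths)) {
      L <- seq_lengths[[s]]
      starts <- seq(0, L - 1, by = window)
      ends <- pmin(starts + window, L)
      pos <- x$pos[x$chrom == s]
      cnt <- tabulate(pmin(floor((pos - 1) / window) + 1, length(starts)),
                      nbins = length(starts))
      out[[s]] <- tibble(chrom = s, win_start = starts, win_end = ends,
                         count = cnt, per_mb = cnt * 1e6 / (ends - starts))
    }
    bind_rows(out)
  } else {
    seqs <- as_seq_vector(x)
    out <- list()
    for (s in names(seqs)) {
      L <- nchar(seqs[[s]])
      starts <- seq(0, L - 1, by = window)
      ends <- pmin(starts + window, L)
      gc <- vapply(seq_along(starts), function(i) {
        w <- substr(seqs[[s]], starts[i] + 1, ends[i])
        bases <- table(factor(strsplit(w, "")[[1]], levels = c("A", "C", "G", "T", "N")))
        atgc <- sum(bases[c("A", "C", "G", "T")])
        if (atgc == 0) NA_real_ else 100 * sum(bases[c("C", "G")]) / atgc
      }, numeric(1))
      out[[s]] <- tibble(chrom = s, win_start = starts, win_end = ends,
                         gc_percent = gc)
    }
    bind_rows(out)
  }
}
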