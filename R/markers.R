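# In-silico PCR placement of sequence-based markers onto assembly
# sequences. A marker is placed where its two primers match on
# opposite strands, facing inward, within the platform's amplicon size
# range; each primer may carry at most 2 mismatches and 2 gaps. Where
# in-silico PCR is ambiguous or empty, an unambiguous top
# sequence-similarity hit of the known amplicon is used as fallback.

#' Describe a marker assay
#'
#' @param name marker name.
#' @param fwd,rev primer sequences (>= 15 bases each).
#' @param platform `"fluidigm"` (amplicon range 10-1000 bp) or
#'   `"other"` (10-5000 bp).
#' @param amplicon known amplicon sequence for fallback placement
#'   (optional).
#' @return a `marker_assay` list.
#' @export
marker_assay <- function(name, fwd, rev, platform = c("other", "fluidigm"),
                         amplicon = NULL) {
  platform <- match.arg(platform)
  if (nchar(fwd) < 15 || nchar(rev) < 15) abort("primers must be >= 15 bases")
  structure(list(name = name, fwd = toupper(fwd), rev = toupper(rev),
                 platform = platform, amplicon = amplicon),
            class = "marker_assay")
}

# all approximate occurrences of `primer` on the forward strand of
# `seq`, with mismatch/gap counts; edit-distance candidates are found
# with indel-aware matching, then refined by alignment to split
# mismatches from gaps
primer_sites <- function(primer, seq, max_mismatch = 2, max_gap = 2) {
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(primer)
  m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch + max_gap,
                                with.indels = TRUE)
  if (length(m) == 0)
    return(tibble(start = integer(0), end = integer(0), mm = integer(0), gaps = integer(0)))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  rows <- purrr::map(seq_along(m), function(i) {
    region <- as.character(m[[i]])
    aln <- Biostrings::pairwiseAlignment(primer, region, type = "global",
                                         substitutionMatrix = sub_mat,
                                         gapOpening = 0, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    gaps <- sum(pa == "-") + sum(sa == "-")
    mm <- sum(pa != sa & pa != "-" & sa != "-")
    tibble(start = BiocGenerics::start(m)[i], end = BiocGenerics::end(m)[i],
           mm = mm, gaps = gaps)
  })
  bind_rows(rows) |>
    filter(.data$mm <= max_mismatch, .data$gaps <= max_gap) |>
    dplyr::distinct(.data$start, .keep_all = TRUE)
}

#' In-silico PCR: find candidate amplicons for a marker assay
#'
#' Searches each sequence for the two primers on opposite strands
#' facing inward, within the platform's amplicon size range, allowing
#' up to `max_mismatch` mismatches and `max_gap` gaps per primer
#' (tracked separately; their sum is the candidate's distance).
#'
#' @param assay a [marker_assay()].
#' @param sequences named character vector / `DNAStringSet` / FASTA path.
#' @param max_mismatch,max_gap per-primer caps.
#' @param size_range amplicon length range; defaults by platform.
#' @return tibble of candidates sorted by distance: `seq_id`, `start`,
#'   `end` (0-based half-open), `strand`, `length`, `mm`, `gaps`,
#'   `dist`.
#' @export
insilico_pcr <- function(assay, sequences, max_mismatch = 2, max_gap = 2,
                         size_range = NULL) {
  stopifnot(inherits(assay, "marker_assay"))
  seqs <- as_seq_vector(sequences)
  size_range <- size_range %||%
    if (assay$platform == "fluidigm") c(10, 1000) else c(10, 5000)
  out <- list()
  for (s in names(seqs)) {
    # plus-strand amplicon: fwd ...... revcomp(rev)
    # minus-strand amplicon: rev ...... revcomp(fwd)
    combos <- list(
      list(left = assay$fwd, right = revcomp(assay$rev), strand = "+"),
      list(left = assay$rev, right = revcomp(assay$fwd), strand = "-")
    )
    for (cb in combos) {
      lhit <- primer_sites(cb$left, seqs[[s]], max_mismatch, max_gap)
      if (nrow(lhit) == 0) next
      rhit <- primer_sites(cb$right, seqs[[s]], max_mismatch, max_gap)
      if (nrow(rhit) == 0) next
      pairs <- tidyr::crossing(dplyr::rename_with(lhit, ~ paste0("l_", .x)),
                               dplyr::rename_with(rhit, ~ paste0("r_", .x))) |>
        mutate(length = .data$r_end - .data$l_start + 1) |>
        filter(.data$r_start > .data$l_end,
               .data$length >= size_range[1], .data$length <= size_range[2])
      if (nrow(pairs) == 0) next
      out[[length(out) + 1]] <- tibble(
        seq_id = s, start = pairs$l_start - 1L, end = pairs$r_end,
        strand = cb$strand, length = pairs$length,
        mm = pairs$l_mm + pairs$r_mm, gaps = pairs$l_gaps + pairs$r_gaps,
        dist = pairs$l_mm + pairs$r_mm + pairs$l_gaps + pairs$r_gaps
      )
    }
  }
  if (length(out) == 0)
    return(tibble(seq_id = character(0), start = integer(0), end = integer(0),
                  strand = character(0), length = integer(0), mm = integer(0),
                  gaps = integer(0), dist = integer(0)))
  bind_rows(out) |> arrange(.data$dist, .data$seq_id, .data$start)
}

#' Ungapped seed-hit search of a known amplicon (fallback placement)
#'
#' Tiles the amplicon with exact non-overlapping seeds and accumulates
#' seed hits per (sequence, diagonal); each hit's score is the number
#' of seed bases supporting that placement.
#'
#' @param amplicon known amplicon sequence.
#' @param sequences target sequences.
#' @param seed_length exact seed length.
#' @return tibble of hits sorted by score descending: `seq_id`, `start`,
#'   `end` (0-based half-open), `score`.
#' @export
amplicon_hits <- function(amplicon, sequences, seed_length = 15) {
  seqs <- as_seq_vector(sequences)
  n <- nchar(amplicon)
  starts <- seq(1, n - seed_length + 1, by = seed_length)
  seeds <- substring(amplicon, starts, starts + seed_length - 1)
  out <- list()
  for (s in names(seqs)) {
    subj <- Biostrings::DNAString(seqs[[s]])
    for (i in seq_along(seeds)) {
      m <- Biostrings::matchPattern(seeds[i], subj)
      if (length(m) == 0) next
      out[[length(out) + 1]] <- tibble(
        seq_id = s,
        diag = BiocGenerics::start(m) - starts[i],
        bases = seed_length
      )
    }
  }
  if (length(out) == 0)
    return(tibble(seq_id = character(0), start = integer(0), end = integer(0),
                  score = integer(0)))
  bind_rows(out) |>
    group_by(.data$seq_id, .data$diag) |>
    summarise(score = sum(.data$bases), .groups = "drop") |>
    mutate(start = pmax(.data$diag, 0L), end = .data$diag + n) |>
    select("seq_id", "start", "end", "score") |>
    arrange(desc(.data$score))
}

#' Decide a marker's placement
#'
#' If exactly one in-silico PCR candidate attains the minimum distance,
#' the marker is placed by ePCR. If there are no candidates and exactly
#' one unambiguous top fallback hit (best score unique by at least one
#' point), it is placed by sequence similarity. Otherwise it is
#' ambiguous (several equally good locations) or unplaced (no evidence).
#'
#' @param candidates tibble from [insilico_pcr()].
#' @param fallback_hits optional tibble from [amplicon_hits()].
#' @return one-row tibble: `status` (`"placed"`, `"ambiguous"`,
#'   `"unplaced"`), `method` (`"epcr"`, `"sequence_hit"`, or `NA`),
#'   `seq_id`, `start`, `end`, `dist`, `reason`.
#' @export
place_marker <- function(candidates, fallback_hits = NULL) {
  unplaced <- function(status, reason) tibble(
    status = status, method = NA_character_, seq_id = NA_character_,
    start = NA_integer_, end = NA_integer_, dist = NA_integer_, reason = reason)
  if (nrow(candidates) > 0) {
    dmin <- min(candidates$dist)
    best <- filter(candidates, .data$dist == dmin)
    if (nrow(best) == 1)
      return(tibble(status = "placed", method = "epcr", seq_id = best$seq_id,
                    start = best$start, end = best$end, dist = best$dist,
                    reason = NA_character_))
    return(unplaced("ambiguous", sprintf("%d ePCR candidates at distance %d",
                                         nrow(best), dmin)))
  }
  if (!is.null(fallback_hits) && nrow(fallback_hits) > 0) {
    fb <- arrange(fallback_hits, desc(.data$score))
    if (nrow(fb) == 1 || fb$score[1] >= fb$score[2] + 1)
      return(tibble(status = "placed", method = "sequence_hit",
                    seq_id = fb$seq_id[1], start = fb$start[1], end = fb$end[1],
                    dist = NA_integer_, reason = NA_character_))
    return(unplaced("ambiguous", "tied top sequence hits"))
  }
  unplaced("unplaced", "no ePCR candidates and no fallback hits")
}
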