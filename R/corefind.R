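# Collapsed / repeated-non-collapsed region detection from
# differential read-mapping coverage.
#
# Reads are mapped in three modes: r0 counts only uniquely-mapping
# reads; r1 reports one randomly chosen locus for multi-mapping reads;
# r2 reports all loci. A collapsed repeat (extra copies in the genome,
# one in the assembly) inflates all three tracks; a correctly assembled
# repeat zeroes r0 while r1 stays near background and r2 inflates.
# At every position r0 <= r1 <= r2.

#' Classification parameters for collapsed/repeat detection
#'
#' @param coll_factor a position is collapse-flagged when each track
#'   exceeds `coll_factor` times its own overall median.
#' @param rnc_r0_max maximum unique-mode coverage for a repeat flag.
#' @param rnc_r1_min minimum random-one-mode coverage for a repeat flag.
#' @param rnc_r2_factor minimum all-hits coverage for a repeat flag, as a
#'   multiple of the overall r2 median.
#' @param merge_gap same-kind regions closer than this many bases are
#'   merged.
#' @param min_region minimum region length kept, in bases.
#' @return a `corefind_params` list.
#' @export
corefind_params <- function(coll_factor = 2.0, rnc_r0_max = 2, rnc_r1_min = 2,
                            rnc_r2_factor = 0.5, merge_gap = 100, min_region = 1) {
  stopifnot(coll_factor > 0, rnc_r2_factor > 0, merge_gap >= 0, min_region >= 1)
  structure(list(coll_factor = coll_factor, rnc_r0_max = rnc_r0_max,
                 rnc_r1_min = rnc_r1_min, rnc_r2_factor = rnc_r2_factor,
                 merge_gap = merge_gap, min_region = min_region),
            class = "corefind_params")
}

new_coverage_tracks <- function(tracks, unmapped = 0L, n_reads = NA_integer_) {
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    stopifnot(length(tr$r0) == length(tr$r1), length(tr$r1) == length(tr$r2))
    if (any(tr$r0 > tr$r1) || any(tr$r1 > tr$r2))
      abort("invalid tracks: mode ordering r0 <= r1 <= r2 violated")
  }
  structure(list(tracks = tracks, unmapped = unmapped, n_reads = n_reads),
            class = "coverage_tracks")
}

#' @export
print.coverage_tracks <- function(x, ...) {
  cat("<coverage_tracks>", length(x$tracks), "sequence(s),",
      sum(vapply(x$tracks, function(t) length(t$r0), numeric(1))), "bp;",
      x$unmapped, "unmapped read(s)\n")
  invisible(x)
}

#' Overall per-track coverage medians
#'
#' @param tracks a `coverage_tracks` object.
#' @param per_sequence if `TRUE`, medians per sequence; otherwise pooled
#'   genome-wide (the default, more stable on short sequences).
#' @return named numeric vector `r0`, `r1`, `r2`, or a tibble of them per
#'   sequence.
#' @export
overall_medians <- function(tracks, per_sequence = FALSE) {
  if (per_sequence) {
    bind_rows(lapply(names(tracks$tracks), function(s) {
      t <- tracks$tracks[[s]]
      tibble(seq_id = s, r0 = median(t$r0), r1 = median(t$r1), r2 = median(t$r2))
    }))
  } else {
    c(r0 = median(unlist(lapply(tracks$tracks, `[[`, "r0"))),
      r1 = median(unlist(lapply(tracks$tracks, `[[`, "r1"))),
      r2 = median(unlist(lapply(tracks$tracks, `[[`, "r2"))))
  }
}

#' Compute three-mode coverage by exact full-length read matching
#'
#' An exact-match mapping emulator for error-free constant-length reads:
#' every full-length exact occurrence of each read (both strands) is a
#' locus. Reads with one locus increment r0, r1 and r2 there; reads with
#' several loci increment r2 at every locus and r1 at one locus chosen
#' uniformly at random (seeded); reads with no locus are counted as
#' unmapped.
#'
#' @param reads reads (tibble with `seq`, character vector, or FASTQ path).
#' @param assembly assembly sequences (named character, `DNAStringSet`,
#'   or FASTA path).
#' @param seed seed for the random-one locus choice.
#' @return a `coverage_tracks` object.
#' @export
coverage_from_reads <- function(reads, assembly, seed = 1) {
  rd <- as_read_vector(reads)
  seqs <- as_seq_vector(assembly)
  if (length(seqs) == 0 || length(rd) == 0) abort("empty reads or assembly")
  set.seed(seed)
  subj <- Biostrings::DNAStringSet(seqs)
  hit_tbl <- list()
  for (w in unique(nchar(rd))) {
    idx <- which(nchar(rd) == w)
    pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(rd[idx]))
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(rd[idx])))
    for (si in seq_along(subj)) {
      for (pd in list(pd_fwd, pd_rev)) {
        m <- Biostrings::matchPDict(pd, subj[[si]])
        st <- Biostrings::startIndex(m)
        nhit <- vapply(st, function(v) length(v %||% integer(0)), integer(1))
        if (sum(nhit) == 0) next
        hit_tbl[[length(hit_tbl) + 1]] <- tibble(
          read = idx[rep(seq_along(nhit), nhit)],
          seq_id = names(seqs)[si],
          start = unlist(st, use.names = FALSE),
          width = w
        )
      }
    }
  }
  hits <- if (length(hit_tbl)) bind_rows(hit_tbl) else
    tibble(read = integer(0), seq_id = character(0), start = integer(0), width = integer(0))
  # forward and reverse matches at the same locus (palindromic reads) are one locus
  hits <- dplyr::distinct(hits, .data$read, .data$seq_id, .data$start, .keep_all = TRUE)
  n_loci <- tabulate(hits$read, nbins = length(rd))
  unmapped <- sum(n_loci == 0)

  lens <- nchar(seqs)
  empty <- lapply(lens, function(L) integer(L))
  cov_of <- function(h) {
    out <- empty
    for (s in unique(h$seq_id)) {
      hs <- h[h$seq_id == s, ]
      ir <- IRanges::IRanges(start = hs$start, width = hs$width)
      out[[s]] <- as.integer(IRanges::coverage(ir, width = lens[[s]]))
    }
    out
  }
  uniq <- hits[n_loci[hits$read] == 1, ]
  multi <- hits[n_loci[hits$read] > 1, ]
  r0 <- cov_of(uniq)
  r2_extra <- cov_of(multi)
  # one uniformly chosen locus per multi-mapping read
  r1_pick <- multi |>
    group_by(.data$read) |>
    dplyr::slice_sample(n = 1) |>
    ungroup()
  r1_extra <- cov_of(r1_pick)
  tracks <- lapply(names(seqs), function(s) list(
    r0 = r0[[s]],
    r1 = r0[[s]] + r1_extra[[s]],
    r2 = r0[[s]] + r2_extra[[s]]
  ))
  names(tracks) <- names(seqs)
  new_coverage_tracks(tracks, unmapped = unmapped, n_reads = length(rd))
}

#' Read a five-column per-base coverage table
#'
#' Tab-delimited dialect: sequence name, 1-based position, r0, r1, r2,
#' with a header line. Missing positions within a sequence are treated
#' as zero coverage with a warning.
#'
#' @param path input TSV path.
#' @return a `coverage_tracks` object.
#' @export
coverage_from_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "cinnn",
                        col_names = c("seq_id", "pos", "r0", "r1", "r2"),
                        skip = 1, progress = FALSE)
  if (nrow(df) == 0) abort("empty coverage table")
  if (any(df$r0 > df$r1) || any(df$r1 > df$r2))
    abort("invalid tracks: mode ordering r0 <= r1 <= r2 violated")
  tracks <- lapply(split(df, df$seq_id), function(d) {
    L <- max(d$pos)
    r0 <- integer(L); r1 <- integer(L); r2 <- integer(L)
    if (nrow(d) < L) warn(sprintf("%d missing position(s) treated as zero coverage", L - nrow(d)))
    r0[d$pos] <- as.integer(d$r0)
    r1[d$pos] <- as.integer(d$r1)
    r2[d$pos] <- as.integer(d$r2)
    list(r0 = r0, r1 = r1, r2 = r2)
  })
  new_coverage_tracks(tracks)
}

#' Write a coverage track set as a five-column table
#' @param tracks a `coverage_tracks`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(tracks, path) {
  df <- bind_rows(lapply(names(tracks$tracks), function(s) {
    t <- tracks$tracks[[s]]
    tibble(seq_id = s, pos = seq_along(t$r0), r0 = t$r0, r1 = t$r1, r2 = t$r2)
  }))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# maximal runs of TRUE in a logical vector -> 0-based half-open intervals
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble(start = starts[r$values], end = ends[r$values])
}

merge_close <- function(iv, gap) {
  if (nrow(iv) <= 1) return(iv)
  iv <- arrange(iv, .data$start)
  out <- iv[1, ]
  for (i in 2:nrow(iv)) {
    if (iv$start[i] - out$end[nrow(out)] <= gap) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], iv$end[i])
    } else {
      out <- bind_rows(out, iv[i, ])
    }
  }
  out
}

#' Classify collapsed and repeated-non-collapsed regions
#'
#' Per-position predicates: a position is collapse-flagged (`coll`) when
#' r0, r1 and r2 each exceed `coll_factor` times their own overall
#' median; repeat-flagged (`rnc`) when r0 is between 0 and `rnc_r0_max`,
#' r1 is at least `rnc_r1_min`, and r2 is at least `rnc_r2_factor` times
#' the overall r2 median. Maximal runs of equal flag become regions;
#' same-kind regions within `merge_gap` bases are merged.
#'
#' @param tracks a `coverage_tracks`.
#' @param params a [corefind_params()].
#' @param per_sequence compute overall medians per sequence instead of
#'   genome-wide.
#' @return tibble of regions: `seq_id`, `start`, `end` (0-based
#'   half-open), `kind`, `copy_number` (ratio of the region's median r2
#'   to the overall r2 median).
#' @export
classify_regions <- function(tracks, params = corefind_params(), per_sequence = FALSE) {
  stopifnot(inherits(tracks, "coverage_tracks"))
  med_all <- overall_medians(tracks, per_sequence = FALSE)
  if (all(unlist(lapply(tracks$tracks, function(t) c(t$r0, t$r1, t$r2))) == 0))
    abort("degenerate input: all coverage tracks are zero")
  med_ps <- if (per_sequence) overall_medians(tracks, per_sequence = TRUE) else NULL
  out <- list()
  for (s in names(tracks$tracks)) {
    t <- tracks$tracks[[s]]
    med <- if (per_sequence) {
      r <- med_ps[med_ps$seq_id == s, ]
      c(r0 = r$r0, r1 = r$r1, r2 = r$r2)
    } else med_all
    if (med["r0"] <= 0)
      abort("overall median of the unique-mapping track is zero; classification is meaningless")
    coll <- t$r0 > params$coll_factor * med["r0"] &
      t$r1 > params$coll_factor * med["r1"] &
      t$r2 > params$coll_factor * med["r2"]
    rnc <- t$r0 >= 0 & t$r0 <= params$rnc_r0_max &
      t$r1 >= params$rnc_r1_min &
      t$r2 >= params$rnc_r2_factor * med["r2"]
    if (med["r0"] >= 2 && any(coll & rnc))
      abort("internal error: position flagged both coll and rnc with median r0 >= 2")
    rnc <- rnc & !coll  # coll takes precedence in low-coverage degenerate cases
    for (kind in c("coll", "rnc")) {
      iv <- runs_of(if (kind == "coll") coll else rnc)
      if (nrow(iv) == 0) next
      iv <- merge_close(iv, params$merge_gap)
      iv <- filter(iv, .data$end - .data$start >= params$min_region)
      if (nrow(iv) == 0) next
      out[[length(out) + 1]] <- mutate(iv, seq_id = s, kind = kind)
    }
  }
  if (length(out) == 0)
    return(tibble(seq_id = character(0), start = integer(0), end = integer(0),
                  kind = character(0), copy_number = numeric(0)))
  regions <- bind_rows(out) |> select("seq_id", "start", "end", "kind") |>
    arrange(.data$seq_id, .data$start)
  regions$copy_number <- vapply(seq_len(nrow(regions)), function(i)
    estimate_copy_number(regions[i, ], tracks, med_r2 = med_all["r2"]), numeric(1))
  regions
}

#' Estimate the copy number of a flagged region
#'
#' The ratio of the region's median all-hits (r2) coverage to the
#' overall r2 median, reported to two decimals.
#'
#' @param region one-row tibble with `seq_id`, `start`, `end` (0-based
#'   half-open).
#' @param tracks a `coverage_tracks`.
#' @param med_r2 overall r2 median; computed genome-wide if missing.
#' @return copy-number estimate (numeric).
#' @export
estimate_copy_number <- function(region, tracks, med_r2 = NULL) {
  med_r2 <- med_r2 %||% overall_medians(tracks)[["r2"]]
  if (med_r2 == 0) abort("overall r2 median is zero; copy number undefined")
  t <- tracks$tracks[[region$seq_id]]
  if (is.null(t) || region$end > length(t$r2) || region$start < 0)
    abort("region outside track bounds")
  unname(round_half_up(median(t$r2[(region$start + 1):region$end]) / med_r2, 2))
}

#' Write flagged regions as BED6
#'
#' Chrom, 0-based start, half-open end, name = kind, score = 100 x copy
#' number capped at 1000, strand ".".
#'
#' @param regions region tibble from [classify_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coll/rnc regions (BED6: chrom start end kind score strand)", con)
  if (nrow(regions) > 0) {
    score <- pmin(1000, round(100 * (regions$copy_number %ifna% 0)))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", regions$seq_id, regions$start,
                       regions$end, regions$kind, score), con)
  }
  invisible(path)
}

#' Read a BED file of flagged regions written by [write_bed()]
#' @param path BED path.
#' @return region tibble.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0)
    return(tibble(seq_id = character(0), start = integer(0), end = integer(0),
                  kind = character(0), copy_number = numeric(0)))
  parts <- strsplit(lines, "\t")
  tibble(seq_id = vapply(parts, `[`, "", 1),
         start = as.integer(vapply(parts, `[`, "", 2)),
         end = as.integer(vapply(parts, `[`, "", 3)),
         kind = vapply(parts, `[`, "", 4),
         copy_number = as.numeric(vapply(parts, `[`, "", 5)) / 100)
}
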