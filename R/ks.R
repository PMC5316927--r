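# Pairwise Ka/Ks estimation (Nei-Gojobori 1986 counting with
# Jukes-Cantor multiple-hit correction), chaining of gene anchors into
# collinear synteny blocks, block-median Ks, Ks histograms and modal
# peak detection.

# Jukes-Cantor correction; undefined at p >= 3/4
jc_correct <- function(p) {
  if (p >= 3 / 4) abort("saturation: proportion of differences >= 3/4, correction undefined")
  if (p == 0) return(0)
  -3 / 4 * log(1 - 4 / 3 * p)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) abort("sequence length is not a multiple of 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Nei-Gojobori (1986) pairwise Ka/Ks with Jukes-Cantor correction
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon
#' fractionally, averaging over the two sequences; counts synonymous
#' and nonsynonymous differences by averaging over all orderings of
#' single-step mutational pathways between differing codons, excluding
#' pathways through stop codons. Proportions are corrected for multiple
#' hits with `d = -(3/4) ln(1 - (4/3) p)`. Codons containing gaps or
#' ambiguity characters, and codon pairs where either codon is a stop,
#' are excluded from counting.
#'
#' @param seq_a,seq_b aligned coding sequences of equal length (multiple
#'   of 3); gap columns (`-`) permitted.
#' @return one-row tibble: `S`, `N` (site counts), `sd_count`,
#'   `nd_count` (difference counts), `ps`, `pn`, `Ks`, `Ka`, `Ka_Ks`,
#'   `n_codons` (countable codon pairs).
#' @export
ng86_pairwise <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) abort("aligned sequences must have equal length")
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  keep <- clean
  keep[clean] <- !is_stop_codon(ca[clean]) & !is_stop_codon(cb[clean])
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) abort("no countable codon pairs in alignment")
  ssites <- syn_sites_table()
  S <- (sum(ssites[ca]) + sum(ssites[cb])) / 2
  N <- 3 * length(ca) - S
  pd <- pair_diff_table()
  d <- pd[paste(ca, cb), , drop = FALSE]
  sd_count <- sum(d[, "sd"]); nd_count <- sum(d[, "nd"])
  ps <- sd_count / S
  pn <- nd_count / N
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  tibble(S = S, N = N, sd_count = sd_count, nd_count = nd_count,
         ps = ps, pn = pn, Ks = Ks, Ka = Ka,
         Ka_Ks = ifelse(Ks > 0, Ka / Ks, NA_real_),
         n_codons = length(ca))
}

#' Ka/Ks for a table of sequence pairs
#'
#' Applies [ng86_pairwise()] to each row; pairs that fail (saturation,
#' no countable codons) get `NA` estimates and a reason.
#'
#' @param pairs tibble with columns `seq_a`, `seq_b` and optionally
#'   `pair_id`.
#' @return the input with estimate columns appended.
#' @export
ng86_table <- function(pairs) {
  pairs <- as_tibble(pairs)
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    tryCatch(
      mutate(ng86_pairwise(pairs$seq_a[i], pairs$seq_b[i]), fail_reason = NA_character_),
      error = function(e) tibble(S = NA_real_, N = NA_real_, sd_count = NA_real_,
                                 nd_count = NA_real_, ps = NA_real_, pn = NA_real_,
                                 Ks = NA_real_, Ka = NA_real_, Ka_Ks = NA_real_,
                                 n_codons = NA_integer_,
                                 fail_reason = conditionMessage(e)))
  })
  dplyr::bind_cols(pairs, bind_rows(res))
}

#' Keep each query gene's best-scoring match per target chromosome
#'
#' The anchor retention rule applied before chaining: for every query
#' gene, the top-scoring hit on each target chromosome is kept (so one
#' gene may retain several hits genome-wide, at most one per
#' chromosome).
#'
#' @param anchors anchor tibble with `gene_a`, `chr_b`, `score`.
#' @return filtered anchor tibble.
#' @export
filter_top_anchors <- function(anchors) {
  anchors |>
    group_by(.data$gene_a, .data$chr_b) |>
    slice_max(.data$score, n = 1, with_ties = FALSE) |>
    ungroup()
}

# dynamic program for one (chr_a, chr_b, orientation) anchor set;
# returns the best chain (indices into `anc`) and its score
best_chain_dp <- function(anc, max_gap, gap_penalty, reverse = FALSE) {
  n <- nrow(anc)
  if (n == 0) return(NULL)
  ord <- order(anc$start_a, anc$start_b)
  anc <- anc[ord, ]
  best <- anc$score
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1)) {
      gap_a <- anc$start_a[i] - anc$end_a[j]
      if (gap_a < 0 || gap_a > max_gap) next
      if (!reverse) {
        gap_b <- anc$start_b[i] - anc$end_b[j]
      } else {
        gap_b <- anc$start_b[j] - anc$end_b[i]
      }
      if (gap_b < 0 || gap_b > max_gap) next
      cand <- best[j] + anc$score[i] - gap_penalty * (gap_a + gap_b)
      if (cand > best[i]) {
        best[i] <- cand
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  chain <- end
  while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
  list(idx = ord[chain], score = best[end])
}

#' Chain collinear anchors into synteny blocks
#'
#' A sparse dynamic program in the style of collinearity chainers:
#' anchors are chained when both genome-A and genome-B coordinates
#' advance (descend, for reverse-orientation chains) with gaps of at
#' most `max_gap` bases on each genome; each chained anchor adds its
#' score minus `gap_penalty` per gap base. Blocks are extracted
#' best-first without anchor reuse, per chromosome pair and
#' orientation, until no chain of at least `min_block` anchors remains.
#'
#' @param anchors tibble with `gene_a`, `chr_a`, `start_a`, `end_a`,
#'   `gene_b`, `chr_b`, `start_b`, `end_b`, `score`, optionally `ks`.
#' @param max_gap maximum per-genome gap between chained anchors (bases).
#' @param gap_penalty score penalty per gap base.
#' @param min_block minimum anchors per reported block.
#' @return tibble of blocks: `block_id`, `chr_a`, `chr_b`, `orientation`,
#'   `n_anchors`, genome spans, `score`, `median_ks` (if `ks` present),
#'   and `anchors` (list-column of the member anchor rows).
#' @export
chain_anchors <- function(anchors, max_gap = 100000, gap_penalty = 0.001,
                          min_block = 6) {
  anchors <- as_tibble(anchors)
  if (nrow(anchors) == 0) {
    return(tibble(block_id = integer(0), chr_a = character(0), chr_b = character(0),
                  orientation = character(0), n_anchors = integer(0),
                  start_a = integer(0), end_a = integer(0),
                  start_b = integer(0), end_b = integer(0),
                  score = numeric(0), median_ks = numeric(0), anchors = list()))
  }
  blocks <- list()
  for (key in unique(paste(anchors$chr_a, anchors$chr_b, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- filter(anchors, .data$chr_a == parts[1], .data$chr_b == parts[2])
    repeat {
      fwd <- best_chain_dp(sub, max_gap, gap_penalty, reverse = FALSE)
      rev <- best_chain_dp(sub, max_gap, gap_penalty, reverse = TRUE)
      cand <- list(forward = fwd, reverse = rev)
      cand <- cand[!vapply(cand, is.null, logical(1))]
      # prefer the higher-scoring orientation, requiring min_block anchors
      cand <- cand[order(-vapply(cand, `[[`, numeric(1), "score"))]
      took <- FALSE
      for (ori in names(cand)) {
        ch <- cand[[ori]]
        if (length(ch$idx) < min_block) next
        memb <- sub[ch$idx, ]
        blocks[[length(blocks) + 1]] <- tibble(
          chr_a = parts[1], chr_b = parts[2], orientation = ori,
          n_anchors = nrow(memb),
          start_a = min(memb$start_a), end_a = max(memb$end_a),
          start_b = min(memb$start_b), end_b = max(memb$end_b),
          score = ch$score,
          median_ks = if ("ks" %in% names(memb)) block_median_ks(memb$ks) else NA_real_,
          anchors = list(memb)
        )
        sub <- sub[-ch$idx, ]
        took <- TRUE
        break
      }
      if (!took || nrow(sub) < min_block) break
    }
  }
  if (length(blocks) == 0) {
    return(tibble(block_id = integer(0), chr_a = character(0), chr_b = character(0),
                  orientation = character(0), n_anchors = integer(0),
                  start_a = integer(0), end_a = integer(0),
                  start_b = integer(0), end_b = integer(0),
                  score = numeric(0), median_ks = numeric(0), anchors = list()))
  }
  bind_rows(blocks) |>
    arrange(.data$chr_a, .data$start_a) |>
    mutate(block_id = row_number()) |>
    select("block_id", dplyr::everything())
}

#' Median Ks of a synteny block
#'
#' Anchors whose Ks is missing (e.g. saturated pairs) are excluded; the
#' median of an even count is the mean of the central two values.
#'
#' @param ks per-anchor Ks values.
#' @return the block median, or `NA` with a warning if every anchor is
#'   missing.
#' @export
block_median_ks <- function(ks) {
  ok <- ks[is.finite(ks)]
  if (length(ok) == 0) {
    warn("all anchors saturated or missing Ks; block dropped")
    return(NA_real_)
  }
  median(ok)
}

#' Bin block-median Ks values into a proportion histogram
#'
#' Half-open bins `[i*w, (i+1)*w)`; proportions are scaled to the total
#' count so they sum to one (comparable across species pairs).
#'
#' @param values non-negative Ks values (typically block medians).
#' @param bin_width bin width in Ks units.
#' @param source optional label for the comparison.
#' @return a `ks_histogram`: tibble with `bin_start`, `bin_mid`, `n`,
#'   `proportion` (dense, contiguous from 0), plus attributes.
#' @export
ks_histogram <- function(values, bin_width = 0.01, source = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no Ks values")
  if (any(values < 0)) abort("negative Ks values are not allowed")
  stopifnot(bin_width > 0)
  idx <- floor(values / bin_width)
  nbin <- max(idx) + 1
  counts <- tabulate(idx + 1, nbins = nbin)
  out <- tibble(bin_start = (seq_len(nbin) - 1) * bin_width,
                bin_mid = (seq_len(nbin) - 0.5) * bin_width,
                n = counts,
                proportion = counts / sum(counts))
  attr(out, "bin_width") <- bin_width
  attr(out, "source") <- source %||% NA_character_
  class(out) <- c("ks_histogram", class(out))
  out
}

#' Find modal peaks of a Ks histogram
#'
#' The proportion profile is smoothed with a centred moving average of
#' `smooth_window` bins (odd; zero-padded at the edges); local maxima
#' with topographic prominence of at least `min_prominence` are
#' reported in ascending Ks, each at its bin centre.
#'
#' @param hist a [ks_histogram()].
#' @param smooth_window odd number of bins for the moving average.
#' @param min_prominence minimum peak prominence (proportion units).
#' @return tibble with `ks_mode`, `height` (smoothed), `prominence`.
#' @export
find_modal_peaks <- function(hist, smooth_window = 5, min_prominence = 0.002) {
  stopifnot(inherits(hist, "ks_histogram"))
  if (smooth_window %% 2 == 0) abort("smooth_window must be odd")
  y <- hist$proportion
  n <- length(y)
  if (smooth_window > n) abort("smooth_window larger than the histogram")
  half <- (smooth_window - 1) / 2
  # edge-value padding: a flat histogram stays flat under smoothing and
  # yields no spurious boundary peaks
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  sm <- vapply(seq_len(n), function(i) mean(ypad[i:(i + 2 * half)]), numeric(1))
  is_max <- vapply(seq_len(n), function(i) {
    if (i == 1) return(n > 1 && sm[1] > sm[2])
    if (i == n) return(sm[n] > sm[n - 1])
    sm[i] > sm[i - 1] && sm[i] >= sm[i + 1]
  }, logical(1))
  peaks <- which(is_max)
  prom <- vapply(peaks, function(p) {
    h <- sm[p]
    side_min <- function(idx_seq) {
      m <- h
      for (i in idx_seq) {
        if (sm[i] > h) return(m)
        m <- min(m, sm[i])
      }
      m
    }
    lmin <- side_min(rev(seq_len(p - 1)))
    rmin <- side_min(seq(p + 1, length.out = n - p))
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  tibble(ks_mode = hist$bin_mid[peaks[keep]],
         height = sm[peaks[keep]],
         prominence = prom[keep])
}
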