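# K-mer frequency histogram and genome-size estimation.
#
# Genome size is estimated as total k-mer frequency divided by the
# depth of the primary (homozygous single-copy) peak of the k-mer
# multiplicity histogram. K-mers are counted canonically (the
# lexicographic minimum of a k-mer and its reverse complement) since
# sequencing is strand-symmetric.

#' Count canonical k-mers in a read set
#'
#' @param reads reads as a tibble with a `seq` column, character vector,
#'   `DNAStringSet`, or FASTA/FASTQ path.
#' @param k odd k-mer size, `1 < k <= 31` (default 17).
#' @return a `kmer_histogram`: list with `k`, `spectrum` (tibble
#'   `multiplicity`, `n_kmers`: the number of distinct canonical k-mers
#'   seen that many times), `total_frequency` (total k-mer occurrences,
#'   equal to the sum over counted reads of `length - k + 1`), and
#'   `n_short_skipped`.
#' @export
count_kmers <- function(reads, k = 17) {
  if (k %% 2 == 0 || k <= 1 || k > 31) abort("k must be odd and in (1, 31]")
  rd <- as_read_vector(reads)
  if (length(rd) == 0) abort("no reads")
  lens <- nchar(rd)
  short <- lens < k
  if (any(short)) {
    warn(sprintf("%d read(s) shorter than k skipped", sum(short)))
    rd <- rd[!short]; lens <- lens[!short]
    if (length(rd) == 0) abort("no reads of length >= k")
  }
  kmers <- unlist(lapply(split(rd, lens), function(batch) {
    L <- nchar(batch[1])
    starts <- seq_len(L - k + 1)
    unlist(lapply(starts, function(s) substr(batch, s, s + k - 1)), use.names = FALSE)
  }), use.names = FALSE)
  # canonicalize on the distinct k-mers only
  occ <- table(kmers)
  uniq <- names(occ)
  rc <- revcomp(uniq)
  canon <- ifelse(uniq <= rc, uniq, rc)
  per_canon <- tapply(as.integer(occ), canon, sum)
  spectrum <- as_tibble(as.data.frame(table(mult = as.integer(per_canon)))) |>
    mutate(multiplicity = as.integer(as.character(.data$mult)),
           n_kmers = as.integer(.data$Freq)) |>
    select("multiplicity", "n_kmers") |>
    arrange(.data$multiplicity)
  out <- list(k = as.integer(k), spectrum = spectrum,
              total_frequency = sum(as.numeric(spectrum$multiplicity) * spectrum$n_kmers),
              n_short_skipped = sum(short))
  class(out) <- "kmer_histogram"
  stopifnot(out$total_frequency == sum(lens - k + 1))
  out
}

#' Assemble a k-mer histogram from a multiplicity spectrum
#'
#' For use when the spectrum was computed externally (e.g. by a k-mer
#' counting tool) and only the histogram arithmetic is needed.
#'
#' @param spectrum tibble/data frame with columns `multiplicity` and
#'   `n_kmers`.
#' @param k k-mer size.
#' @return a `kmer_histogram`.
#' @export
kmer_histogram <- function(spectrum, k = 17) {
  spectrum <- as_tibble(spectrum)
  stopifnot(all(c("multiplicity", "n_kmers") %in% names(spectrum)),
            all(spectrum$n_kmers >= 0), all(spectrum$multiplicity >= 1))
  spectrum <- arrange(spectrum, .data$multiplicity)
  structure(list(k = as.integer(k), spectrum = spectrum,
                 total_frequency = sum(as.numeric(spectrum$multiplicity) * spectrum$n_kmers),
                 n_short_skipped = 0L),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("<kmer_histogram> k =", x$k, "| total frequency",
      format(x$total_frequency, big.mark = " "), "| multiplicities",
      min(x$spectrum$multiplicity), "-", max(x$spectrum$multiplicity), "\n")
  invisible(x)
}

#' Locate the primary coverage peak of a k-mer histogram
#'
#' The low-multiplicity error region (sequencing-error k-mers seen once
#' or a few times) is excluded by scanning multiplicities in ascending
#' order until the first local minimum of the counts; the peak is the
#' multiplicity with the global maximum count at or beyond that
#' minimum. The peak search uses a light centred moving average
#' (`smooth_window` multiplicities) so that counting noise on small
#' inputs does not shift the reported mode; the error-region scan uses
#' the raw counts.
#'
#' @param hist a `kmer_histogram`.
#' @param smooth_window odd moving-average window for the peak search
#'   (1 = no smoothing).
#' @return the primary peak depth (integer multiplicity).
#' @export
primary_peak <- function(hist, smooth_window = 3) {
  stopifnot(inherits(hist, "kmer_histogram"))
  sp <- hist$spectrum
  if (nrow(sp) == 0) abort("empty histogram")
  mmax <- max(sp$multiplicity)
  dense <- numeric(mmax)
  dense[sp$multiplicity] <- sp$n_kmers
  # first local minimum scanning ascending multiplicities
  if (mmax < 3)
    abort("no primary peak resolvable: histogram has no local minimum beyond the error region")
  vmin <- NA_integer_
  for (i in 2:mmax) {
    if (dense[i] < dense[i - 1] && i < mmax && dense[i] <= dense[i + 1]) {
      vmin <- i
      break
    }
  }
  if (is.na(vmin))
    abort("no primary peak resolvable: histogram has no local minimum beyond the error region")
  if (smooth_window %% 2 == 0) abort("smooth_window must be odd")
  half <- (smooth_window - 1) / 2
  # zero out the error region so its spike cannot leak into the smoothed
  # peak search
  dwork <- dense
  dwork[seq_len(vmin - 1)] <- 0
  padded <- c(rep(0, half), dwork, rep(0, half))
  smoothed <- vapply(seq_len(mmax), function(i) mean(padded[i:(i + 2 * half)]),
                     numeric(1))
  region <- vmin:mmax
  peak <- region[which.max(smoothed[region])]
  if (peak == vmin || dense[peak] == 0)
    abort("no primary peak resolvable above the error region")
  as.integer(peak)
}

#' Estimate genome size from a k-mer histogram
#'
#' Applies the estimator `genome size = total k-mer frequency / primary
#' peak depth`, rounded to the nearest base.
#'
#' @param hist a `kmer_histogram`, or the total k-mer frequency as a
#'   bare number.
#' @param peak_depth primary peak depth; defaults to [primary_peak()].
#' @return estimated genome size in bases (numeric, integer-valued).
#' @export
estimate_genome_size <- function(hist, peak_depth = NULL) {
  if (inherits(hist, "kmer_histogram")) {
    total <- hist$total_frequency
    if (is.null(peak_depth)) peak_depth <- primary_peak(hist)
  } else {
    total <- as.numeric(hist)
    if (is.null(peak_depth)) abort("peak_depth is required when passing a bare total frequency")
  }
  if (peak_depth < 1) abort("peak_depth must be >= 1")
  round(total / peak_depth)
}
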