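#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number desc slice_max
#' @importFrom stats median setNames rnorm runif
#' @importFrom utils head tail
NULL

# round-half-up at a fixed number of decimals; base round() is banker's
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%ifna%` <- function(x, y) ifelse(is.na(x), y, x)

DNA_BASES <- c("A", "C", "G", "T")

# fast reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# i.i.d. random DNA with a given GC fraction
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# coerce assorted sequence inputs (named character, DNAStringSet, FASTA path)
# to a named character vector
as_seq_vector <- function(x, default_prefix = "seq") {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) == 1 && file.exists(x) &&
             grepl("\\.(fa|fasta|fna|fas)$", x, ignore.case = TRUE)) {
    out <- as.character(Biostrings::readDNAStringSet(x))
    names(out) <- sub("\\s.*$", "", names(out))
  } else if (is.character(x)) {
    out <- x
  } else {
    abort("cannot interpret input as DNA sequences")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    names(out) <- paste0(default_prefix, seq_along(out))
  }
  out
}

# reads from: tibble with a `seq` column, character vector, DNAStringSet,
# or a FASTA/FASTQ file path
as_read_vector <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot("seq" %in% names(reads))
    return(reads$seq)
  }
  if (inherits(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)$", reads, ignore.case = TRUE)) "fastq" else "fasta"
    return(as.character(Biostrings::readDNAStringSet(reads, format = fmt)))
  }
  if (is.character(reads)) return(reads)
  abort("cannot interpret input as reads")
}
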