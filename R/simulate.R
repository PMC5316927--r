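#' Specify a repeat feature to plant in a synthetic genome
#'
#' Two kinds of planted feature are supported. A *collapsed* repeat is
#' present in `copies_in_truth` copies in the genome the reads are drawn
#' from, but only `copies_in_assembly` copies in the assembly -- the
#' situation an assembler produces when it collapses near-identical
#' repeats. A *repeated_non_collapsed* repeat is correctly assembled:
#' the same number of copies (at least two) in both.
#'
#' @param kind `"collapsed"` or `"repeated_non_collapsed"`.
#' @param unit_length length of one repeat copy, in bases.
#' @param copies_in_truth copy number in the underlying genome (>= 2).
#' @param copies_in_assembly copy number in the assembly (>= 1).
#' @param identity sequence identity between planted copies (1 = exact
#'   duplicates; values < 1 introduce substitutions into non-first copies).
#' @return a `planted_feature` spec list.
#' @export
planted_feature <- function(kind = c("collapsed", "repeated_non_collapsed"),
                            unit_length = 1000,
                            copies_in_truth = 3,
                            copies_in_assembly = if (kind == "collapsed") 1 else copies_in_truth,
                            identity = 1) {
  kind <- match.arg(kind)
  stopifnot(unit_length >= 1, copies_in_truth >= 2, copies_in_assembly >= 1,
            identity > 0, identity <= 1)
  if (kind == "collapsed" && copies_in_assembly >= copies_in_truth)
    abort("collapsed feature requires copies_in_assembly < copies_in_truth")
  if (kind == "repeated_non_collapsed" && copies_in_assembly != copies_in_truth)
    abort("repeated_non_collapsed feature requires equal copy numbers")
  structure(list(kind = kind, unit_length = as.integer(unit_length),
                 copies_in_truth = as.integer(copies_in_truth),
                 copies_in_assembly = as.integer(copies_in_assembly),
                 identity = identity),
            class = "planted_feature")
}

# sample `k` non-overlapping intervals of width `w` inside [0, L), avoiding
# `avoid` (tibble start/end, 0-based half-open); rejection sampling
sample_intervals <- function(k, w, L, avoid = NULL) {
  taken <- avoid %||% tibble(start = integer(0), end = integer(0))
  out <- tibble(start = integer(0), end = integer(0))
  tries <- 0
  while (nrow(out) < k) {
    tries <- tries + 1
    if (tries > 5000 * k) abort("could not place features: genome too small for the requested features")
    s <- sample.int(L - w + 1, 1) - 1L
    cand <- c(s, s + w)
    all_t <- bind_rows(taken, out)
    if (nrow(all_t) == 0 || all(cand[2] <= all_t$start | cand[1] >= all_t$end)) {
      out <- bind_rows(out, tibble(start = s, end = s + as.integer(w)))
    }
  }
  out
}

mutate_copy <- function(seq, identity) {
  if (identity >= 1) return(seq)
  n <- nchar(seq)
  nmut <- round((1 - identity) * n)
  if (nmut == 0) return(seq)
  pos <- sample.int(n, nmut)
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
  paste(ch, collapse = "")
}

#' Simulate a genome with planted collapsed / retained repeats
#'
#' Builds an assembly sequence of exactly `length` bases with i.i.d. base
#' composition at the requested GC, plants the requested repeat features
#' (replacing background sequence, so assembly length is preserved), and
#' derives the *truth* genome reads are drawn from: identical to the
#' assembly except that collapsed features gain their missing extra
#' copies, inserted at random positions outside planted intervals.
#'
#' @param length assembly length in bases; must be at least 10x the total
#'   planted footprint.
#' @param features list of [planted_feature()] specs.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed; all randomness is derived from it.
#' @return a `genome_truth` object: list with `assembly` and `truth`
#'   (named character vectors), `features` manifest tibble (one row per
#'   feature, assembly coordinates as a list-column of 0-based half-open
#'   intervals), and `seed`.
#' @export
simulate_genome <- function(length, features = list(), gc = 0.5, seed = 1) {
  stopifnot(gc > 0, gc < 1, length >= 1)
  if (inherits(features, "planted_feature")) features <- list(features)
  footprint <- sum(vapply(features, function(f) f$unit_length * f$copies_in_assembly, numeric(1)))
  if (length(features) > 0 && length < 10 * footprint)
    abort("genome length must be at least 10x the planted feature footprint")
  set.seed(seed)

  assembly <- random_dna(length, gc)
  manifest <- tibble(
    feature_id = character(0), kind = character(0), unit_length = integer(0),
    copies_in_truth = integer(0), copies_in_assembly = integer(0),
    unit_seq = character(0), coords = list()
  )
  placed <- tibble(start = integer(0), end = integer(0))
  for (i in seq_along(features)) {
    f <- features[[i]]
    unit <- random_dna(f$unit_length, gc)
    iv <- sample_intervals(f$copies_in_assembly, f$unit_length, length, avoid = placed)
    iv <- arrange(iv, .data$start)
    for (j in seq_len(nrow(iv))) {
      copy <- if (j == 1) unit else mutate_copy(unit, f$identity)
      substr(assembly, iv$start[j] + 1, iv$end[j]) <- copy
    }
    placed <- bind_rows(placed, iv)
    manifest <- bind_rows(manifest, tibble(
      feature_id = sprintf("feat%02d", i), kind = f$kind,
      unit_length = f$unit_length, copies_in_truth = f$copies_in_truth,
      copies_in_assembly = f$copies_in_assembly, unit_seq = unit,
      coords = list(iv)
    ))
  }

  # truth genome: insert the extra copies of collapsed features at random
  # break points outside all planted intervals
  insertions <- tibble(at = integer(0), seq = character(0))
  for (i in seq_len(nrow(manifest))) {
    extra <- manifest$copies_in_truth[i] - manifest$copies_in_assembly[i]
    if (extra <= 0) next
    f <- features[[i]]
    for (e in seq_len(extra)) {
      repeat {
        at <- sample.int(length + 1, 1) - 1L  # 0..length, between-base gap
        inside <- any(at > placed$start & at < placed$end)
        if (!inside) break
      }
      copy <- mutate_copy(manifest$unit_seq[i], f$identity)
      insertions <- bind_rows(insertions, tibble(at = at, seq = copy))
    }
  }
  truth <- assembly
  if (nrow(insertions) > 0) {
    insertions <- arrange(insertions, .data$at)
    pieces <- character(0)
    prev <- 0L
    for (j in seq_len(nrow(insertions))) {
      pieces <- c(pieces, substr(assembly, prev + 1, insertions$at[j]), insertions$seq[j])
      prev <- insertions$at[j]
    }
    pieces <- c(pieces, substr(assembly, prev + 1, length))
    truth <- paste(pieces, collapse = "")
  }

  out <- list(assembly = c(seq1 = assembly), truth = c(seq1 = truth),
              features = manifest, gc = gc, seed = seed)
  class(out) <- "genome_truth"
  stopifnot(nchar(truth) == length +
              sum((manifest$copies_in_truth - manifest$copies_in_assembly) * manifest$unit_length))
  out
}

#' @export
print.genome_truth <- function(x, ...) {
  cat("<genome_truth> assembly", sum(nchar(x$assembly)), "bp; truth",
      sum(nchar(x$truth)), "bp;", nrow(x$features), "planted feature(s)\n")
  invisible(x)
}

#' Simulate uniform-depth error-free (or substitution-noised) reads
#'
#' Single-end reads of constant length drawn uniformly from the truth
#' genome, both strands equiprobable. The read count is
#' `round(depth * truth_length / read_length)`.
#'
#' @param truth a `genome_truth` object or named character vector of
#'   sequences to read from.
#' @param depth target fold-coverage (> 0).
#' @param read_length read length in bases, shorter than every sequence.
#' @param error_rate per-base substitution rate in `[0, 0.5)`.
#' @param seed integer seed.
#' @return tibble with columns `read_id`, `seq`, `src_seq`, `src_start`
#'   (1-based), `strand`.
#' @export
simulate_reads <- function(truth, depth, read_length = 100, error_rate = 0, seed = 1) {
  seqs <- if (inherits(truth, "genome_truth")) truth$truth else as_seq_vector(truth)
  stopifnot(depth > 0)
  if (error_rate < 0 || error_rate >= 0.5) abort("error_rate must be in [0, 0.5)")
  lens <- nchar(seqs)
  if (any(read_length >= lens)) abort("read_length must be shorter than every sequence")
  set.seed(seed)
  total <- sum(lens)
  n <- round(depth * total / read_length)
  src <- sample(names(seqs), n, replace = TRUE, prob = lens / total)
  start <- vapply(lens[src] - read_length + 1, function(m) sample.int(m, 1), integer(1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  rd <- substring(seqs[src], start, start + read_length - 1)
  rd[strand == "-"] <- revcomp(rd[strand == "-"])
  if (error_rate > 0) {
    rd <- vapply(rd, function(s) {
      hit <- which(runif(read_length) < error_rate)
      if (length(hit) == 0) return(s)
      ch <- strsplit(s, "")[[1]]
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  tibble(read_id = sprintf("read%07d", seq_len(n)), seq = unname(rd),
         src_seq = unname(src), src_start = unname(start), strand = strand)
}

#' Write reads to FASTQ
#'
#' Constant quality `I` (Phred 40); the simulator does not model quality.
#'
#' @param reads tibble from [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4 * nrow(reads))
  lines[seq(1, by = 4, length.out = nrow(reads))] <- paste0("@", reads$read_id)
  lines[seq(2, by = 4, length.out = nrow(reads))] <- reads$seq
  lines[seq(3, by = 4, length.out = nrow(reads))] <- "+"
  lines[seq(4, by = 4, length.out = nrow(reads))] <-
    strrep("I", nchar(reads$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences to FASTA
#' @param seqs named character vector or `genome_truth`.
#' @param path output path.
#' @param which for a `genome_truth`, `"assembly"` or `"truth"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, which = c("assembly", "truth")) {
  if (inherits(seqs, "genome_truth")) seqs <- seqs[[match.arg(which)]]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Simulate codon-sequence pairs diverged to a target Ks
#'
#' Each pair starts from a random stop-free codon sequence; one member
#' then receives synonymous single-base substitutions at distinct codons
#' until the expected Nei-Gojobori Ks (after Jukes-Cantor correction)
#' matches `target_ks`. No nonsynonymous changes and no stop codons are
#' introduced, so Ka = 0 by construction.
#'
#' @param n_pairs number of pairs.
#' @param target_ks target synonymous divergence (>= 0); rejected where
#'   the implied proportion of synonymous differences exceeds 0.70,
#'   close to the Jukes-Cantor saturation bound of 3/4.
#' @param n_codons codons per sequence (>= 30).
#' @param seed integer seed.
#' @return tibble with `pair_id`, `seq_a`, `seq_b`, `n_syn_sub` (the
#'   realized substitution count manifest).
#' @export
simulate_codon_pairs <- function(n_pairs, target_ks, n_codons = 300, seed = 1) {
  stopifnot(n_pairs >= 1, n_codons >= 30)
  if (target_ks < 0) abort("target_ks must be >= 0")
  ps_target <- 0.75 * (1 - exp(-4 / 3 * target_ks))
  if (ps_target >= 0.70)
    abort("target_ks is beyond the saturation range of the Jukes-Cantor correction")
  set.seed(seed)
  ssites <- syn_sites_table()
  sense <- sense_codons()
  rows <- purrr::map(seq_len(n_pairs), function(i) {
    codons <- sample(sense, n_codons, replace = TRUE)
    S <- sum(ssites[codons])
    n_sub <- round(ps_target * S)
    cods_b <- codons
    if (n_sub > 0) {
      mutable <- which(vapply(codons, function(cd) length(syn_neighbours(cd)) > 0, logical(1)))
      n_sub <- min(n_sub, length(mutable))
      at <- sample(mutable, n_sub)
      cods_b[at] <- vapply(codons[at], function(cd) {
        nb <- syn_neighbours(cd)
        nb[sample.int(length(nb), 1)]
      }, character(1))
    }
    tibble(pair_id = sprintf("pair%04d", i),
           seq_a = paste(codons, collapse = ""),
           seq_b = paste(cods_b, collapse = ""),
           n_syn_sub = n_sub)
  })
  bind_rows(rows)
}

#' Plant a synteny anchor set with known ploidy structure
#'
#' Lays out the requested events on disjoint segments of a reference
#' sequence. An event of multiplicity *m* covering fraction *f* of the
#' genome produces *m* stacked copies of collinear synteny blocks over a
#' segment of length `f * ref_length`, each block a run of at least
#' `min_block` gene anchors; per-anchor Ks values are drawn around the
#' event's median. The returned truth depth profile gives the planted
#' per-depth genome fractions that a depth-profiling step should recover.
#'
#' @param ref_length reference length in bases.
#' @param events list of lists / tibble rows with `multiplicity` (>= 1),
#'   `fraction` of the genome, and `median_ks`.
#' @param seed integer seed.
#' @param min_block minimum anchors per block.
#' @param block_span target block footprint in bases.
#' @param anchor_width anchor (gene) width in bases.
#' @param ks_sd standard deviation of per-anchor Ks around the event median.
#' @return list with `anchors` (tibble: gene_a, chr_a, start_a, end_a,
#'   gene_b, chr_b, start_b, end_b, score, ks, block_id_truth),
#'   `depth_truth` (tibble: depth, fraction), `blocks_truth`, and the
#'   generation parameters.
#' @export
plant_synteny <- function(ref_length, events = list(), seed = 1,
                          min_block = 6, block_span = 5000,
                          anchor_width = 300, ks_sd = 0.03) {
  if (is.data.frame(events)) events <- purrr::transpose(events)
  fracs <- vapply(events, function(e) e$fraction, numeric(1))
  mults <- vapply(events, function(e) as.numeric(e$multiplicity), numeric(1))
  if (length(events) > 0) {
    if (sum(fracs) > 1 + 1e-9) abort("event fractions must sum to at most 1")
    if (any(mults < 1)) abort("multiplicities must be >= 1")
  }
  set.seed(seed)
  anchors <- list(); blocks <- list()
  depth_counts <- numeric(0)
  cursor <- 0L
  blk_n <- 0L
  for (ei in seq_along(events)) {
    e <- events[[ei]]
    seg_len <- round(e$fraction * ref_length)
    seg_start <- cursor
    cursor <- cursor + seg_len
    n_blocks <- max(1, floor(seg_len / block_span))
    bounds <- round(seq(seg_start, seg_start + seg_len, length.out = n_blocks + 1))
    for (bi in seq_len(n_blocks)) {
      b0 <- bounds[bi]; b1 <- bounds[bi + 1]
      span <- b1 - b0
      n_anch <- max(min_block, floor(span / (2 * anchor_width)))
      astart <- round(seq(b0, b1 - anchor_width, length.out = n_anch))
      for (copy in seq_len(e$multiplicity)) {
        blk_n <- blk_n + 1L
        # one query sequence per planted block so collinear runs are
        # separated on the query side, as distinct blocks are in real data
        qchr <- sprintf("q_e%d_c%d_b%d", ei, copy, bi)
        qoff <- 0L
        ks <- pmax(0, rnorm(n_anch, e$median_ks, ks_sd))
        anchors[[length(anchors) + 1]] <- tibble(
          gene_a = sprintf("ref_g%05d_%d", astart, copy),
          chr_a = "ref", start_a = as.integer(astart),
          end_a = as.integer(astart + anchor_width),
          gene_b = sprintf("%s_g%04d", qchr, seq_len(n_anch)),
          chr_b = qchr,
          start_b = as.integer(qoff + (astart - b0)),
          end_b = as.integer(qoff + (astart - b0) + anchor_width),
          score = 100, ks = ks, block_id_truth = blk_n
        )
        blocks[[length(blocks) + 1]] <- tibble(
          block_id_truth = blk_n, chr_a = "ref", start_a = b0, end_a = b1,
          chr_b = qchr, event = ei, median_ks_truth = e$median_ks
        )
      }
    }
    depth_counts[as.character(e$multiplicity)] <-
      (depth_counts[as.character(e$multiplicity)] %ifna% 0) + seg_len / ref_length
  }
  covered <- if (length(events)) sum(fracs) else 0
  depth_truth <- tibble(depth = 0L, fraction = 1 - covered)
  if (length(depth_counts) > 0) {
    depth_truth <- bind_rows(depth_truth,
      tibble(depth = as.integer(names(depth_counts)), fraction = unname(depth_counts)))
  }
  depth_truth <- depth_truth |> group_by(.data$depth) |>
    summarise(fraction = sum(.data$fraction), .groups = "drop") |>
    filter(.data$fraction > 0) |> arrange(.data$depth)
  list(anchors = if (length(anchors)) bind_rows(anchors) else
         tibble(gene_a = character(0), chr_a = character(0), start_a = integer(0),
                end_a = integer(0), gene_b = character(0), chr_b = character(0),
                start_b = integer(0), end_b = integer(0), score = numeric(0),
                ks = numeric(0), block_id_truth = integer(0)),
       blocks_truth = if (length(blocks)) bind_rows(blocks) else tibble(),
       depth_truth = depth_truth,
       params = list(ref_length = ref_length, min_block = min_block,
                     block_span = block_span, seed = seed))
}

#' Simulate modal Ks observations from an event tree
#'
#' For every unordered tip pair, emits an ortholog observation equal to
#' the Ks path-sum from each tip to their most recent common ancestor;
#' for every duplication node and each of its descendant tips, emits a
#' paralog observation equal to twice the tip-to-event path-sum.
#' Gaussian noise of standard deviation `noise_sd` is added to each.
#'
#' @param tree an [event_tree()] with known branch `length`s.
#' @param noise_sd observation noise standard deviation (Ks units).
#' @param seed integer seed.
#' @return tibble with `kind` (`"ortholog"` / `"paralog"`), `tip_a`,
#'   `tip_b` (second tip, or the event node for paralog rows), `observed`.
#' @export
simulate_modal_distances <- function(tree, noise_sd = 0, seed = 1) {
  stopifnot(inherits(tree, "event_tree"))
  if (any(is.na(tree$nodes$length[!is.na(tree$nodes$parent)])))
    abort("tree branch lengths must be known to simulate observations")
  set.seed(seed)
  tips <- tree_tips(tree)
  obs <- list()
  if (length(tips) >= 2) {
    pairs <- utils::combn(tips, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      m <- tree_mrca(tree, a, b)
      d <- path_length(tree, a, m) + path_length(tree, b, m)
      obs[[length(obs) + 1]] <- tibble(kind = "ortholog", tip_a = a, tip_b = b, observed = d)
    }
  }
  dups <- tree$nodes$node[tree$nodes$type %in% c("wgd", "wgt")]
  for (dn in dups) {
    for (t in tree_tips(tree, below = dn)) {
      d <- 2 * path_length(tree, t, dn)
      obs[[length(obs) + 1]] <- tibble(kind = "paralog", tip_a = t, tip_b = dn, observed = d)
    }
  }
  out <- bind_rows(obs)
  out$observed <- out$observed + rnorm(nrow(out), 0, noise_sd)
  out
}
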