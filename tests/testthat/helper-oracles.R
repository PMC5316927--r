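# Independent oracles, deliberately written as plain brute-force
# enumerations with no code shared with the package internals.

GC_TABLE <- as.list(Biostrings::GENETIC_CODE)

oracle_aa <- function(codon) GC_TABLE[[codon]]

oracle_is_stop <- function(codon) identical(oracle_aa(codon), "*")

# fraction of synonymous sites of one codon: for each position, the
# share of the three possible base changes that preserve the amino acid
# (changes producing a stop codon count as nonsynonymous)
oracle_syn_sites <- function(codon) {
  aa <- oracle_aa(codon)
  total <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!oracle_is_stop(mut) && oracle_aa(mut) == aa) total <- total + 1 / 3
    }
  }
  total
}

# all permutations of a vector, recursively
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# average (syn, nonsyn) difference counts between two sense codons over
# all stop-free single-step pathways; all pathways if every one is blocked
oracle_codon_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, NULL)[[1]] != strsplit(cb, NULL)[[1]])
  if (length(pos) == 0) return(c(0, 0))
  tally <- list()
  for (order in oracle_perms(pos)) {
    cur <- ca
    sdn <- c(0, 0)
    blocked <- FALSE
    for (step in seq_along(order)) {
      p <- order[step]
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (step < length(order) && oracle_is_stop(nxt)) blocked <- TRUE
      if (oracle_aa(cur) == oracle_aa(nxt)) sdn[1] <- sdn[1] + 1 else sdn[2] <- sdn[2] + 1
      cur <- nxt
    }
    tally[[length(tally) + 1]] <- list(sdn = sdn, blocked = blocked)
  }
  ok <- Filter(function(t) !t$blocked, tally)
  if (length(ok) == 0) ok <- tally
  Reduce(`+`, lapply(ok, `[[`, "sdn")) / length(ok)
}

# full pairwise Ka/Ks by direct enumeration
oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ok <- ok & !vapply(ifelse(ok, ca, "AAA"), oracle_is_stop, logical(1)) &
    !vapply(ifelse(ok, cb, "AAA"), oracle_is_stop, logical(1))
  ca <- ca[ok]; cb <- cb[ok]
  Sa <- sum(vapply(ca, oracle_syn_sites, numeric(1)))
  Sb <- sum(vapply(cb, oracle_syn_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  diffs <- Reduce(`+`, lapply(seq_along(ca), function(i) oracle_codon_diffs(ca[i], cb[i])))
  ps <- diffs[1] / S
  pn <- diffs[2] / N
  jc <- function(p) if (p == 0) 0 else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, ps = ps, pn = pn, Ks = jc(ps), Ka = jc(pn))
}

# exhaustive best-chain search by depth-first enumeration of every
# valid chain (both orientations), for small anchor sets
oracle_best_chain_score <- function(anc, max_gap, gap_penalty) {
  n <- nrow(anc)
  if (n == 0) return(-Inf)
  ord <- order(anc$start_a, anc$start_b)
  anc <- anc[ord, ]
  best <- -Inf
  compat <- function(j, i, reverse) {
    ga <- anc$start_a[i] - anc$end_a[j]
    gb <- if (!reverse) anc$start_b[i] - anc$end_b[j] else anc$start_b[j] - anc$end_b[i]
    if (ga < 0 || gb < 0 || ga > max_gap || gb > max_gap) return(NA_real_)
    gap_penalty * (ga + gb)
  }
  extend <- function(last, score, reverse) {
    best <<- max(best, score)
    if (last == n) return()
    for (k in (last + 1):n) {
      pen <- compat(last, k, reverse)
      if (!is.na(pen)) extend(k, score + anc$score[k] - pen, reverse)
    }
  }
  for (reverse in c(FALSE, TRUE)) {
    for (i in seq_len(n)) extend(i, anc$score[i], reverse)
  }
  best
}

# naive per-base depth counting
oracle_depth_counts <- function(intervals, len) {
  depth <- integer(len)
  for (i in seq_len(nrow(intervals))) {
    idx <- (intervals$start[i] + 1):intervals$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# random sense-codon sequence pairs with scattered substitutions (both
# synonymous and nonsynonymous), guaranteed stop-free
random_codon_pair <- function(n_codons, n_mut) {
  sense <- names(Filter(function(a) a != "*", GC_TABLE))
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  for (m in seq_len(n_mut)) {
    repeat {
      i <- sample(n_codons, 1)
      p <- sample(3, 1)
      cand <- b[i]
      substr(cand, p, p) <- sample(c("A", "C", "G", "T"), 1)
      if (!oracle_is_stop(cand)) { b[i] <- cand; break }
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# random anchor set on a pair of sequences, for chaining trials
random_anchor_set <- function(n, span = 10000, reverse_some = TRUE) {
  tibble::tibble(
    gene_a = paste0("ga", seq_len(n)), chr_a = "A",
    start_a = sort(sample.int(span, n)),
    gene_b = paste0("gb", seq_len(n)), chr_b = "B",
    start_b = sample.int(span, n),
    score = sample(50:150, n, replace = TRUE)
  ) |>
    dplyr::mutate(end_a = start_a + sample(50:200, n, replace = TRUE),
                  end_b = start_b + sample(50:200, n, replace = TRUE)) |>
    dplyr::select(gene_a, chr_a, start_a, end_a, gene_b, chr_b, start_b, end_b, score)
}
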