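# Codon-level machinery shared by the Ka/Ks estimator and the codon-pair
# simulator: synonymous site fractions and per-codon-pair substitution
# counts under the Nei-Gojobori (1986) counting scheme.
#
# Conventions (stated once, used consistently):
#  * the standard genetic code (Biostrings::GENETIC_CODE);
#  * single-base changes to a stop codon count as nonsynonymous when
#    tallying synonymous site fractions;
#  * for codon pairs differing at >1 position, synonymous/nonsynonymous
#    difference counts are averaged over all orderings of single-step
#    mutational pathways, excluding pathways that pass through a stop
#    codon (if every pathway is blocked, all are used and a warning is
#    raised -- this cannot occur for sense-codon pairs under the
#    standard code but is handled defensively).

.codon_env <- new.env(parent = emptyenv())

all_codons <- function() {
  b <- DNA_BASES
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

is_stop_codon <- function(codon) {
  codon_aa(codon) == "*"
}

# the three single-base neighbours of `codon` at `pos`
codon_neighbours <- function(codon, pos) {
  ref <- substr(codon, pos, pos)
  vapply(setdiff(DNA_BASES, ref), function(b) {
    out <- codon
    substr(out, pos, pos) <- b
    out
  }, character(1), USE.NAMES = FALSE)
}

# fraction of synonymous sites per codon (0..3); stop codons get NA
syn_sites_table <- function() {
  if (!is.null(.codon_env$syn_sites)) return(.codon_env$syn_sites)
  codons <- all_codons()
  s <- vapply(codons, function(cd) {
    if (is_stop_codon(cd)) return(NA_real_)
    aa <- codon_aa(cd)
    tot <- 0
    for (pos in 1:3) {
      nb <- codon_neighbours(cd, pos)
      # change to a stop codon counts as nonsynonymous
      tot <- tot + sum(codon_aa(nb) == aa & !is_stop_codon(nb)) / 3
    }
    tot
  }, numeric(1))
  .codon_env$syn_sites <- s
  s
}

# average (synonymous, nonsynonymous) difference counts between two sense
# codons over all stop-free single-step pathways
codon_pair_diffs <- function(ca, cb) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  aa_of <- function(x) codon_aa(x)
  perms <- if (length(pos) == 1) list(pos) else
    if (length(pos) == 2) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  paths <- lapply(perms, function(order) {
    cur <- ca
    steps <- character(0)
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      steps <- c(steps, paste(cur, nxt))
      cur <- nxt
    }
    steps
  })
  path_ok <- vapply(paths, function(steps) {
    inter <- vapply(strsplit(steps, " "), `[`, character(1), 2)
    inter <- inter[-length(inter)]  # final codon is cb, known sense
    !any(is_stop_codon(inter))
  }, logical(1))
  if (!any(path_ok)) {
    warn("all mutational pathways pass through a stop codon; using all")
    path_ok[] <- TRUE
  }
  counts <- vapply(paths[path_ok], function(steps) {
    sn <- c(0, 0)
    for (st in strsplit(steps, " ")) {
      if (aa_of(st[1]) == aa_of(st[2])) sn[1] <- sn[1] + 1 else sn[2] <- sn[2] + 1
    }
    sn
  }, numeric(2))
  out <- rowMeans(counts)
  c(sd = out[1], nd = out[2])
}

# lazily built lookup of pair difference counts over all sense-codon pairs,
# keyed "CODON1 CODON2"
pair_diff_table <- function() {
  if (!is.null(.codon_env$pair_diffs)) return(.codon_env$pair_diffs)
  sense <- all_codons()[!is_stop_codon(all_codons())]
  keys <- as.vector(outer(sense, sense, paste))
  mat <- matrix(0, nrow = length(keys), ncol = 2,
                dimnames = list(keys, c("sd", "nd")))
  idx <- 0L
  for (ca in sense) {
    for (cb in sense) {
      idx <- idx + 1L
      if (ca != cb) mat[idx, ] <- codon_pair_diffs(ca, cb)
    }
  }
  .codon_env$pair_diffs <- mat
  mat
}

sense_codons <- function() {
  cds <- all_codons()
  cds[!is_stop_codon(cds)]
}

# synonymous single-step sense neighbours of a sense codon
syn_neighbours <- function(codon) {
  aa <- codon_aa(codon)
  nb <- unlist(lapply(1:3, codon_neighbours, codon = codon))
  nb[codon_aa(nb) == aa & !is_stop_codon(nb)]
}
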