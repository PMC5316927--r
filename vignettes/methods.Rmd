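---
title: "Methods: dating whole-genome duplications and validating assemblies with wgdkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating whole-genome duplications and validating assemblies with wgdkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdkit)
```

`wgdkit` bundles the computations behind a polyploidy-aware genome
analysis: synonymous-divergence (Ks) estimation, synteny block
chaining, modal-peak dating of duplication events, synteny coverage
depth as ploidy evidence, k-mer genome sizing, and read-coverage
diagnostics for assembly collapse. This vignette records the models,
the parameter choices, the numerical decisions, and what the synthetic
test bed does and does not demonstrate.

## Ka/Ks estimation

Pairwise Ka and Ks are computed by the Nei–Gojobori (1986) counting
method on in-frame codon alignments. Each codon contributes a
fractional count of synonymous sites: at each of its three positions,
the share of the three possible base changes that preserve the amino
acid (changes producing a stop codon are counted as nonsynonymous).
Site totals are averaged over the two sequences, so `S + N = 3 x`
(countable codons) holds per alignment. Differences between codons
that differ at more than one position are averaged over all orderings
of single-step mutational pathways; pathways passing through a stop
codon are excluded (should every pathway be blocked — impossible for
sense-codon pairs under the standard code — all are used with a
warning). The proportions `ps = Sd/S` and `pn = Nd/N` are corrected
for multiple hits with the Jukes–Cantor transform
`d = -(3/4) ln(1 - (4/3) p)`, which is undefined at `p >= 3/4`; such
saturated pairs raise an error and are excluded (and counted) at the
block level.

A maximum-likelihood codon-model estimator (codeml-style) would give
slightly different values at high divergence; the counting estimator
is deterministic, closed-form, and exactly reproducible, which is what
the test architecture needs. Externally computed Ks values can be
supplied alongside anchors (a `ks` column on the anchor table) and
flow through chaining, histograms and peaks unchanged.

Codon pairs containing gaps or ambiguity characters, and pairs where
either codon is a stop, are excluded pairwise per codon — an
alignment-quality decision the estimator takes silently but reports
through `n_codons`.

## Synteny blocks and modal peaks

Anchors (homologous gene pairs with coordinates in two genomes) are
chained by the standard sparse dynamic program over anchors sorted by
genome-A position: anchor *i* extends a chain ending at *j* when both
genomes advance (genome B descends, for reverse-orientation chains)
with per-genome gaps of at most `max_gap` bases; the chain score adds
the anchor's similarity score minus `gap_penalty` per gap base. Chains
are extracted best-first without anchor reuse, per chromosome pair,
until no chain of `min_block` anchors remains — mirroring how
collinearity chainers behave in practice. Correctness is tested
against exhaustive enumeration of every valid chain on small anchor
sets. Before chaining, the retention rule `filter_top_anchors()` keeps
each query gene's best hit per target chromosome, so one gene can
retain several hits genome-wide (one per chromosome) — reciprocal-best
filtering is deliberately not applied.

Defaults: `max_gap = 100` kb (collinear gene spacing in plant genomes
rarely exceeds tens of kb; synthetic data uses 20 kb to match its
denser layout), `gap_penalty = 0.001` per base (small relative to
anchor scores of ~100, so gaps break ties but do not dominate),
`min_block = 6` anchors (short spurious collinear runs are common
below ~5 anchors).

Block Ks is the median of the block's anchor Ks values (even counts:
mean of the central two); saturated anchors are dropped and a block
with no finite Ks is dropped with a warning. Medians are binned into
half-open bins `[iw, (i+1)w)` of width `w = 0.01` Ks and normalised to
proportions so comparisons with different block counts are
comparable. Peaks are found on a centred moving average
(`smooth_window = 5` bins) and reported at bin centres when their
topographic prominence reaches `min_prominence = 0.002`; the histogram
is padded with its edge values before smoothing so a flat profile
yields no boundary artifacts. These three constants are not prescribed
by the underlying method; they were fixed once at values that resolve
peaks ~0.05 Ks apart without reporting shot noise, and all peak tests
run at these defaults.

## Event-tree chronology

The species/duplication history is a rooted tree whose tips are
genomes, whose internal nodes are speciations or duplication events
(WGD/WGT), and whose root is itself a duplication (the oldest event
considered). Duplication nodes are *unary*: they sit on a lineage
branch without bifurcating the species tree. Every branch length, in
Ks units, is an unknown. Each observed modal Ks value contributes one
linear equation: an ortholog peak between tips X and Y equals the
branch-sum over both tip-to-MRCA paths; a paralog peak between a tip
and an ancestral event E equals **twice** the tip-to-E path, because
both post-duplication paralog lineages reside in the same genome and
are approximated by the same branches. "Old ortholog" peaks that pass
through the root duplication are encoded as orthologs with the MRCA
forced to the root. Design-matrix entries are therefore always 0, 1
or 2.

The system is solved by least squares (QR), which degrades gracefully
to over-determined noisy inputs and reports the residual norm; an
exactly consistent system is recovered with zero residual. Rank
deficiency raises an error naming unresolved branches rather than
returning a pseudo-inverse answer, because an under-determined
chronology is a study-design problem, not a numerical one. Negative
solved lengths (possible under noise) are clipped to zero with a
warning and flagged.

Rooting at a duplication matters for identifiability: ortholog
distances alone never separate the two branches incident to the basal
speciation (only their sum enters any tip-pair path), while root
paralog observations do. The random tree generator used in simulation
studies therefore roots every tree at a WGD node, matching how such
trees are rooted in practice.

Ages: with the root calibrated (58 Mya by default — the assumed age of
the radiation that immediately followed the root duplication), node
ages are assigned by per-lineage proportional scaling, `age(n) =
cal x mean over descendant tips t of Ks(t→n)/Ks(t→root)`. This is a
lineage-wise strict-clock conversion, averaged across descendant tips
to damp rate variation; per-branch rates (Ks/My) are reported so rate
heterogeneity is visible rather than hidden. Tips sit at age 0, ages
decrease monotonically root-to-tip, and a two-observation reduction
(paralog peaks 0.30 and 0.74 on one lineage) dates the younger event
at `58 x 0.15/0.37 = 23.5` Mya. Richer multi-species observation sets
shift such estimates by a few My, so single-lineage reductions should
be read as magnitude checks, not final dates.

## Synteny coverage depth

Block footprints on a reference are stacked per base (run-length
encoded; verified against naive per-base counting) and summarised as
the fraction of the genome at each depth. Depth counts *block*
intervals, not anchors, matching how per-base coverage tools are
applied to block BED files. For self-comparisons the trivial
main-diagonal self-match (identical coordinates on both sides) can be
excluded, since every base trivially matches itself at depth one.

## K-mer genome size

Canonical k-mers (lexicographic minimum of a k-mer and its reverse
complement; sequencing is strand-symmetric) are counted at `k = 17`,
and genome size is estimated as `total k-mer frequency / primary peak
depth`, rounded to the nearest base. The primary peak is located after
excluding the low-multiplicity error region: counts are scanned in
ascending multiplicity to the first local minimum, and the peak is the
count maximum beyond it, taken on a lightly smoothed spectrum
(3-multiplicity moving average, with the error region zeroed first) so
that counting noise cannot displace the mode by a bin. On genuinely
monotone spectra no peak is resolvable and an error is raised rather
than a guess returned.

Accuracy is limited by peak discretisation: a +-1 error on a peak at
depth `c` moves the estimate by ~`1/c`. At 17-mer depth ~34 (reads at
40x) this is ~3%, and the finite-sample mode of a small (10 kb) test
genome additionally jitters by a couple of multiplicities; tests
therefore assert the peak within +-2 of the expected k-mer depth
`C (L - k + 1)/L` and the size estimate within 5%. Heterozygosity and
repeat peaks are not modelled (no mixture fitting); the estimator
assumes a dominant single-copy peak.

## Collapsed and repeated regions from three-mode coverage

Reads are mapped in three modes — unique only (`r0`), one random locus
per multi-mapper (`r1`), all loci (`r2`) — so `r0 <= r1 <= r2`
everywhere, and `sum(r1)` equals the total mapped bases. A collapsed
repeat (n copies in the genome, fewer in the assembly) inflates all
three tracks at the assembled copy; a correctly assembled repeat
family zeroes `r0` across its copies (no read is unique), keeps `r1`
near background in expectation, and inflates `r2` by the copy number.

Classification is per position, then run-based: a position is `coll`
when `r0`, `r1` and `r2` each exceed `coll_factor = 2` times their own
overall median; `rnc` when `r0 <= 2`, `r1 >= 2` and `r2 >= 0.5 x` the
overall `r2` median. Each mode is compared against *its own* overall
median: a single pooled median would make the `r2` test almost
vacuous in repeat-rich genomes. The `r2 = 0.5 x median` condition is
read as a lower bound screening out low-coverage junk — strict
equality would match almost nothing. Maximal runs of equal flag become
regions and same-kind regions within `merge_gap = 100` bp are merged;
no region-level median re-test is applied after merging. Overall
medians are genome-wide by default (stable on short sequences), with a
per-sequence option matching per-chromosome processing. Copy number is
the region's median `r2` over the genome-wide `r2` median — the
formula is a package choice; the ratio-to-median is the simplest
estimator consistent with the track semantics.

Boundary resolution is limited by the read length: a read partially
overlapping a repeat still maps uniquely, so flagged regions shrink by
up to one read length at each edge. Recall accounting
(`planted_recall()`) therefore trims this fuzz before measuring
overlap. A two-fold collapse sits exactly at the `> 2 x median`
boundary in expectation and is not reliably detectable; the
synthetic suite plants three-fold and larger collapses and documents
this as a sensitivity limit.

Mapping itself is an exact-match emulator over both strands (built on
constant-width dictionary matching), appropriate for the error-free
synthetic reads; real data enter through the five-column per-base
coverage table (`sequence, position, r0, r1, r2`, 1-based) produced by
external aligners run in the three modes.

## Assembly, map, marker and window utilities

N50 follows the cumulative-half convention on lengths sorted
descending, reporting both the rank (`n50_count`) and the length.
Printed percentages round half-up at the presentation layer only.
Genetic-map totals sum per-group maximum positions; the mean interval
divides by (loci - groups), i.e. by the number of marker intervals —
on realistic inputs dividing by loci rounds to the same two decimals,
so the choice is documented but rarely decisive. Window tracks tile
non-overlapping 100-kb windows from position 0, scale counts to per-Mb
by each window's true width (the final partial window is not
under-weighted), and compute GC% over non-N bases.

In-silico PCR accepts up to 2 mismatches and 2 gaps per primer —
tracked separately, summed into a unit-cost edit distance for ranking
— with platform amplicon ranges of 10–1000 bp (Fluidigm) or
10–5000 bp (other). A marker is placed when exactly one candidate
attains the minimum distance; otherwise an unambiguous top
similarity hit of the known amplicon (best score unique by at least
one point, from ungapped seed matching) is used; ePCR wins whenever
both are available. Every marker ends placed, ambiguous or unplaced.

## The synthetic test bed

The generator produces: genomes with i.i.d. base composition at a
chosen GC and planted repeat features (exact duplicates by default; an
identity parameter below 1 stresses the unique-mapping mode);
single-end error-free constant-length reads at uniform depth
(`round(depth x length / read_length)` reads, uniform positions, both
strands); codon pairs built by placing synonymous substitutions at
distinct codons until the expected counting-estimator Ks matches a
target; anchor tables whose blocks tile disjoint reference segments at
planted multiplicities with per-anchor Ks drawn
`N(median, sd = 0.03)`; and modal-distance observations equal to
path-sums plus Gaussian noise. Every output validates against its own
manifest, and identical seeds give byte-identical outputs.

What this does **not** emulate: sequencing error models and quality
strings, paired-end inserts, indels, GC-dependent coverage bias,
diverged (as opposed to exact) repeat families, anchor noise
(spurious or missing anchors, tandem duplications), or rate variation
across lineages beyond observation noise. Passing tests therefore
demonstrate the correctness of the computations under their stated
models, not robustness to the full messiness of real sequencing data;
real-data use enters through the same interfaces (coverage tables,
anchor TSVs, external Ks columns) where those effects are upstream.

Problem sizes were chosen so the whole suite runs on a laptop-scale
budget: 30–60 kb genomes at 20x for classification, 10 kb at 40–80x
for k-mer sizing, 1–4 Mb references with ~300–700 planted blocks for
synteny, 200–1000 codon pairs, and 50 replicates for noisy chronology
studies. Each is large enough that the tested tolerances are
comfortably away from shot noise, as the property tests verify.

## Known limitations

* The Ks estimator saturates at `ps >= 3/4`; deep events (Ks beyond
  ~2) are not datable this way.
* Chronology assumes the event-tree topology is known and correct;
  only branch lengths are estimated, and dating assumes lineage-wise
  constant rates between calibration and tips.
* The classifier's thresholds are calibrated to uniform-coverage
  data; strong coverage bias would require renormalising the tracks
  first.
* The demo pipeline's genome-size stage draws its own 40x read set:
  at the 20x used for classification, the 17-mer peak sits near depth
  17, where +-1 peak discretisation alone is a ~6% size error.
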