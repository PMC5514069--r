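---
title: "Calling essential genes from transposon insertion sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling essential genes from transposon insertion sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tradisr)
```

## The problem and the model

Transposon directed insertion-site sequencing (TraDIS) pools tens of
thousands of independent transposon mutants of a bacterium, sequences across
every transposon-genome junction, and maps each junction to a chromosomal
base. A gene whose disruption is lethal (or severely impairs growth) cannot
contribute viable mutants to the pool, so its span is depleted of insertions.
With a library dense enough that every tolerating gene has been hit, the
absence of insertions becomes statistical evidence of essentiality.

The per-gene statistic is the **insertion index**: the number of unique
insertion sites in the gene divided by gene length. Two refinements matter:

* **3' exclusion.** Insertions in the final 10% of a coding sequence often
  leave a functional truncated protein, so sites in the 3' 10% of each gene
  (strand-aware) are excluded from the numerator. The denominator stays the
  full annotated length — the index is "sites per gene length" in the
  literal sense; the alternative (0.9·L denominator) only rescales all
  indices by a common factor, and the classification is equivariant to
  common rescaling (this is asserted by a test).
* **Unique sites, not read counts.** Read multiplicity reflects PCR and
  pooling depth, not independent insertion events. A site is a base with at
  least one junction-mapped read; by default both strands collapse to one
  site, the conservative choice for a transposon that duplicates its target
  site. A per-strand mode is retained for QC.

Across genes the index distribution is bimodal: a spike at zero (essential
genes plus sampling zeros) and a broad non-essential mode. We model the two
parts with gamma distributions:

1. A Gaussian-kernel density estimate (Silverman's bandwidth, the default of
   `stats::density`) locates the modes. Mode candidates below 5% of the
   tallest mode's height are treated as tail noise. If fewer than two modes
   remain, fitting stops with an error: a unimodal index distribution means
   the library is not saturated enough to separate the classes, and no
   threshold should be derived from it.
2. The **valley** (anti-mode) is the density minimum between the two largest
   modes; ties break toward the smaller index. Indices below the valley form
   the essential component, the rest the non-essential component.
3. Each component is fitted by gamma maximum likelihood
   (`fitdistrplus::fitdist`). Because the gamma excludes zero, zero indices
   are replaced by ε = 1/(2·genome length) — about half of one "could not be
   smaller" site — *for fitting only*; the raw index is kept everywhere
   else. Indices are mean-normalised before optimisation (gamma shape is
   scale-invariant; the rate is rescaled back), which keeps the optimiser
   well-conditioned at insertion-index magnitudes of 10^-3^. A component
   that is numerically constant falls back to an exponential with the
   observed mean.
4. Per gene, the log2 likelihood ratio
   LLR = log₂ f~non~(I)/f~ess~(I) is computed; LLR(0) = −∞ by convention
   (no insertions is maximal evidence of essentiality). A gene is
   **essential** when LLR < −2, **non-essential** when LLR > +2, otherwise
   **ambiguous**. The orientation makes "LLR below −2 means essential" read
   naturally.

The index values where the LLR crosses the two thresholds are reported as
`derived_ess_cutoff` and `derived_noness_cutoff`. They are *outputs* of the
fit — they move with library density — and are located by a 4,000-point grid
scan refined with `uniroot` (tolerance 10^-12^, so the root is exact to well
below the grid spacing). For a saturated library of the scale this package
simulates they land at a few × 10^-3^, the same order as published TraDIS
analyses.

Two curation flags annotate (never silently reclassify) the calls:
`uneven_flag` marks genes whose insertions all sit in one terminal bin
(≤ 20% of the gene) while the remaining 80% is unexpectedly empty (expected
sites ≥ 3 under the library's global density) — an automated surrogate for
the manual inspection step that catches 3'-biased disruption patterns; and
`excluded_repeat` marks genes in multi-copy regions, where exact mapping
discards multimapping reads and an insertion-free span is an artefact, not
evidence.

## Read processing contract

`read_filter_policy()` encodes the processing applied before a read can
contribute: a 10 bp transposon prefix is trimmed; reads shorter than 42 bp
after trimming are dropped; when qualities are available, at least 96% of
bases must reach PHRED 30; matching is exact (no mismatches); reads matching
more than one locus are flagged multimapping and excluded from profiles.
The built-in locator (`locate_reads_exact()`) is an exact-match aligner for
synthetic and small libraries — real sequencing runs are expected to be
mapped by an external aligner and ingested as SAM/BAM (flags 0x4, 0x100,
0x800 honoured; mapping quality 0 treated as multimapping) or as per-base
plot tracks. The insertion point is the transposon-junction base: the
5'-most reference base of a forward alignment, the 3'-most of a reverse one.

## What the simulator emulates

`library_sim_config()` defaults encode the study conditions this package
targets: a 2.42 Mbp circular chromosome; 1,985 genes (54 tRNA at 77 bp, 6
rRNA at 1.5-3 kb, the rest CDS with gamma-distributed lengths rescaled to an
overall mean of 1,099 bp, placed without overlap); an essential fraction of
0.228 sampled uniformly over genes; 58,000 insertion mutants (colonies)
sequenced to a depth of 2,000,000 reads; a target of 46,000 distinct
insertion sites (one per ~52 bp); an ori:ter insertion gradient of 2.5; and
a 1.46× insertion-weight elevation in top-quartile A+T windows (1 kb).

Design choices a user should know:

* **Colonies versus reads.** The number of insertion events in the pool
  (`n_insertions`) and the sequencing depth (`seq_depth`) are distinct.
  Profiles and essentiality use one read per colony; rarefaction operates on
  read-level site draws at full sequencing depth, because saturation is a
  statement about sequencing the pool to exhaustion (at ~43 reads per
  mutant the terminal slope of the curve is numerically zero), not about
  the colony count.
* **Candidate-site thinning.** Drawing 58,000 sites from all 2.42 M bases
  would give ~57,000 distinct sites — nearly no site collisions. Real Tn5
  libraries show strong target-site preference, so insertions are restricted
  to a candidate subset of positions; the subset size (~120,000, about one
  per 20 bp) is calibrated by bisection so the *expected* distinct-site
  count under weighted multinomial sampling, computed directly from the
  weight vector before any sampling, equals the target. The realised yield
  then lands within a few percent of 46,000.
* **Gradient shape.** Insertion weight declines linearly with circular
  distance from the origin. The configured `ori_ter_ratio` is the ratio of
  *octant means* (insertions per gene around ori versus around ter), which
  is how such gradients are reported; under a linear gradient the endpoint
  ratio R~e~ relates to the octant-mean ratio R~o~ by
  R~o~ = (15R~e~+1)/(R~e~+15), which the generator inverts. Octants are
  anchored with octant 1 *centred* on the origin and octant 5 on the
  terminus, and genes are assigned by midpoint. Octant means count read
  multiplicities: unique-site counts saturate and compress the gradient.
* **Essentiality in truth.** Essential genes carry zero insertion weight
  across their 5' 90%; their 3' 10% can be hit, as in real libraries. This
  is the operational definition — essentiality means no viable insertion
  mutants are recovered.
* **Reads.** Each read is `read_length` (50 bp) of genomic sequence
  downstream of the junction, 5'-tagged with the 10 bp transposon prefix,
  so a trimmed read is 50 bp and passes the 42 bp cutoff. Base qualities
  are uniform Q40; sequencing error is not modelled.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing errors and quality heterogeneity,
PCR jackpotting, genuine repeat families (multimapping arises only if the
random genome happens to repeat a read-length substring), fitness effects
short of lethality (every non-essential gene tolerates insertions equally),
operon polarity, and conditionally essential genes. The recovery numbers
(sensitivity/specificity ≈ 0.99 at the study scale) are therefore an upper
bound on what identical settings achieve on real libraries.

## QC analytics

* `rarefaction()` subsamples the read-level site draws without replacement
  at a ladder of depths (default 15 levels, 3 replicates, seeded) and
  reports the ratio of the slope over the final 10% of the curve to the
  initial slope. Values ≪ 1 mean additional sequencing would find almost no
  new sites.
* `octant_density()` reports genes and mean insertions per gene for the
  eight origin-anchored arcs described above; gene counts are conserved by
  construction. Note that per-gene means inherit gene-length composition
  noise (~4% per octant at 250 genes/octant), so octant-to-octant scatter
  of ±10% is expected even for a flat library.
* `at_bias()` ranks fixed windows (default 1 kb) by A+T fraction (N bases
  excluded from numerator and denominator) and reports the percent
  elevation of mean insertion density in top-quartile windows over the
  rest. Window-level normalisation decouples the statistic from gene
  density; an insertion-free profile yields an explicit undefined result.

## Comparative layer

Protein families are built from all-against-all local alignments
(Smith-Waterman, BLOSUM62, gap open 10 / extend 0.5 via
`Biostrings::pairwiseAlignment`): an edge requires ≥ 50% identity and ≥ 50%
coverage of either sequence — read as max(coverage~query~,
coverage~subject~), the inclusive interpretation — in both directions; the
cross-phylum mode lowers identity to 20%. BLAST E-values are not reproduced
by the built-in aligner; externally computed 12-column tabular hits
(E-value-filtered on read-in) are the faithful replication path for
published analyses. The Markov Cluster Algorithm is implemented directly
(column-stochastic matrix with self-loops, alternating expansion and
inflation with pruning at 10^-5^, default inflation 2.0, deterministic
iteration order, convergence to numerical idempotence with non-convergence
an error); families are the connected components of the limiting matrix's
support, which provably coincide with graph components when the graph is
disconnected. Core sets follow the standard definitions: core = present in
all genomes, extended core = present in ≥ 80% of genomes (guarding against
incompletely sequenced drafts), single-copy core = core with exactly one
member per genome (the orthologue/paralogue filter). Overlap reports round
percentages to integers as in prose; functional-category tables report one
decimal and tally unassigned genes explicitly.

## Problem sizes and determinism

All randomness is routed through explicit integer seeds; every generator is
byte-deterministic given its configuration. The test suite exercises unit
behaviour on 3-200 kb toy chromosomes and the full study scale (2.42 Mbp,
58,000 insertions, five seeds) for the recovery claims; proteome panels use
4-8 genomes × 12-40 families, sizes at which the all-vs-all alignment stays
in seconds. The acceptance script repeats the five full-scale runs plus a
2,000-gene mixture recovery in about a minute on one CPU.

## Known limitations

* The GenBank reader is minimal: single-contig flat files with plain or
  `complement()` single-span locations; `join()` spans are not supported
  (use GFF3 + FASTA for such annotations).
* The exact-match locator does not match reads spanning the circular
  origin; the simulator keeps insertion sites one read length clear of the
  sequence ends.
* `fit_insertion_model()` requires ≥ 100 genes and a genuinely bimodal
  index distribution; sparse or shallow libraries fail with an explicit
  error rather than returning unstable thresholds.
* Manual curation of unevenly disrupted genes in published analyses is a
  judgement call; `unevenness_flag()` is a declared surrogate with a fixed
  rule, not a reconstruction of any particular curator's decisions.
* Full-scale replication from deposited sequencing runs (ENA ERR877647 /
  ERR877656 against CP000303.1, with an external aligner and pre-computed
  similarity tables) is documented via `replication_benchmarks()` — 453
  essential genes, a 106-gene three-taxon essential core — but is not part
  of the desk-scale suite.
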