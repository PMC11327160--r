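---
title: "Inferring polyploidy histories and karyotype trajectories from gene order"
author: "karyevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring polyploidy histories and karyotype trajectories from gene order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevol)
```

## The problem

Flowering-plant genomes carry layered records of ancient polyploidy: a
whole-genome duplication (WGD, x2) or triplication (WGT, x3) copies every
chromosome, after which post-polyploid diploidization erodes the evidence
through biased gene loss (fractionation) and chromosome rearrangement —
end-to-end joining (EEJ), nested chromosome fusion (NCF), reciprocal
translocation of chromosome arms (RTA), and inversions. Reading that record
from extant gene orders requires several cooperating inferences, and this
package implements the full chain:

1. **Synteny**: chain homologous gene pairs into collinear blocks on gene
   *rank* coordinates (order along the chromosome), after c-score filtering
   of the homolog table.
2. **Ks dating**: estimate synonymous divergence per anchor pair with the
   Nei–Gojobori (NG86) counting method, represent each block by its median
   Ks, and date polyploidy events by fitting a Gaussian mixture to the Ks
   sample with BIC model selection.
3. **Ploidy**: count syntenic depth (blocks covering each gene) in both
   directions of a genome comparison, read the modal depth ratio, and
   decompose it into an ordered product of x2/x3 events constrained by the
   number of post-reference Ks peaks.
4. **Karyotype**: paint extant chromosomes by ancestral proto-chromosomes,
   classify fusion signatures (EEJ, NCF, RTA, fission), reconstruct an
   ancestral karyotype from a conserved post-WGD genome, and intersect
   trajectories across lineages.
5. **Fractionation**: assign genes to subgenomes of a shared WGD, rank
   subgenomes least/most-fractionated (LF/MF), build a core set of
   orthogroups (CSO) and test retention/loss asymmetry, and classify gene
   duplication modes (WGD/TD/PD/TRD/DSD).

Because real sequenced genomes are not bundled, every stage is exercised
against a seeded genome-evolution simulator whose ground truth (ancestral
gene, proto-chromosome, per-event subgenome, duplication mode) is carried
alongside the simulated gene orders.

## Gene order, not base pairs

All structural inference operates on gene ranks. Base-pair coordinates are
kept in `GenomeTable` (0-based, half-open; BED native, GFF3 converted on
read) solely for reporting, and the simulator regenerates them from ranks
after every operation. This matches dot-plot practice, where a "position"
is a gene index, and removes any dependence on intergenic distances that
the simulator does not model.

## The simulator and what it emulates

`simulateAncestor()` creates single-copy genes on proto-chromosomes; every
gene founds its own family, which makes expected depth ratios analytically
predictable. Operations then transform a `GenomeSimulation`:

* `applyPolyploidy(multiplicity, ageKs)` labels copies (A/B/C) and appends
  the label to each gene's *copy path*. A WGT is a single x3 event, not two
  nested x2 events.
* `applyFusion("EEJ"|"NCF")`, `applyRta()`, `applyInversion()` rearrange
  gene order; the chromosome-count identity
  `n = n0 x (product of multiplicities) - #EEJ - #NCF` is property-tested.
* `fractionate(retention)` keeps each labelled copy with its subgenome's
  probability. Families drawn as all-lost are *redrawn*, so every ancestral
  family survives; this conditioning lifts the realized marginal retention
  to `r / (1 - prod(1 - r))`, and the tests assert that conditional
  expectation, not the unconditional binomial mean.
* `applySmallScaleDuplication()` plants TD (rank-adjacent), PD (within the
  proximal window, default 10 ranks), TRD (copy moved to another
  chromosome, parent kept at the ancestral locus) and DSD (random distant
  position) copies. At most one small-scale event is planted per ancestral
  family, keeping the ground truth unambiguous. DSD families additionally
  lose their ortholog in the other lineages of a scenario: a dispersed
  duplicate is, by definition, one whose ancestral locus can no longer be
  traced — with the outgroup copy present, the DupGen-style precedence
  would necessarily read the pair as transposed.
* `generateCodonPair(nCodons, targetDs)` builds a stop-free codon sequence
  pair differing only by synonymous substitutions, placed on
  fourfold-degenerate third positions first, until the NG86 estimate first
  reaches the target. It provides an independent substrate for validating
  the estimator.

Pairwise Ks is not produced by a substitution clock: each homolog pair
draws from Normal(event age, 0.1 x age), truncated at zero, where the event
is the oldest point at which the two copy paths disagree. This reproduces
the unimodal per-event Ks peaks that mixture fitting consumes, at desk
scale. Similarity scores are synthesized as `100 x (1 - ks/ksMax)` so the
c-score filter has realistic best-hit structure without any alignment.

What the simulator does *not* emulate: nucleotide-level evolution beyond
synonymous edits, transposable elements, intergenic/bp dynamics, gene
conversion between homoeologs, rate variation across lineages, and
ancestral multi-copy families. Passing tests therefore demonstrate the
correctness of the inference machinery under clean, unimodal divergence
and complete annotation; they do not certify performance on genomes with
saturated Ks, pervasive tandem arrays, or noisy homology calls.

## Numerical and procedural choices

* **c-score**: pair (a,b) is kept iff
  `score >= threshold x max(best(a), best(b))`. The classical 0.99 screen
  is appropriate for 1:1 ortholog detection; depth analyses default to
  0.5 because every surviving subgenome copy must keep its anchors, and
  equal-age copies differ in score only by Ks noise.
* **Chaining**: sparse dynamic programming per chromosome pair and
  orientation; chain score is anchor count; both rank gaps must be
  <= `maxGap` (default 25); blocks shorter than `minBlockSize` (default 5)
  are discarded; anchors are used at most once, extracted greedily
  best-chain-first with deterministic tie-breaks (parallel first, then
  chromosome ids, then start rank). Tandem arrays are collapsed to their
  best-scoring member beforehand, and an anchor linking two members of one
  array is dropped outright. For self-comparisons a diagonal band
  (`maskDiagonal`) can be excluded so that dense local duplicates cannot
  chain into fake collinear blocks.
* **NG86**: fractional site counts per codon with changes-to-stop excluded
  from the possible-change denominator; multi-nucleotide codon differences
  averaged over all orderings of single steps, excluding paths through
  stops (with a fallback to all paths when none is stop-free); Jukes–Cantor
  correction; pS >= 3/4 flags saturation rather than raising an error.
* **Mixture fitting**: EM with k-means-seeded restarts (10), tolerance
  1e-6, at most 500 iterations, standard-deviation floor 1e-4; k chosen by
  BIC over 1..kMax; input filtered to (0.005, 3.0] to trim allele-level
  noise and saturation. Identical seeds give identical models. Block
  medians are the default fitting stream (the per-pair stream is the
  fallback for small block sets).
* **Depth and ratios**: depth counts *blocks*, not anchors, per gene; the
  mode is taken over covered genes only, since fractionation-induced zeros
  would otherwise dominate; a ratio is only reported when covered fraction
  >= 0.3 on both sides. Between two genomes that share an old event, the
  orthologous ratio is read after `filterBlocksByKs()` removes blocks at
  or beyond that event's age — this is what keeps a shared triplication
  from reading 3:3.
* **Decomposition**: ordered factorizations over {2,3} with exactly one
  factor per post-reference Ks peak; ambiguity (e.g. 6:1 with two peaks:
  3x2 vs 2x3) is surfaced, never silently resolved — a comparison against
  an intermediate relative is the sanctioned resolver. Shared-vs-
  independent event calls match events across lineages by multiplicity and
  age (tolerance 0.15 Ks, configurable) and check the classification
  against the observed cross ratio.
* **Painting and classification**: per-gene score-weighted proto votes;
  unanchored genes inherit the nearest assigned neighbour; runs below
  `minSegmentGenes` (default 10) merge into the better-supported flank
  (ties toward the preceding segment). An X–Y–X segment pattern is an NCF;
  adjacent distinct protos whose segments reach both of their proto's
  termini (within `telomereWindow` ranks) are an EEJ; reciprocally
  exchanged partial arms are one RTA; a split without reciprocity is a
  fission; anything else is UNRESOLVED with its signature attached. The
  default `telomereWindow` is 5 ranks; analyses of strongly fractionated
  genomes should widen it (the batteries use 10) because at retention 0.6
  the chance that all 5 terminal proto genes are lost is about 1% per
  chromosome end, which would misread an EEJ as partial. An NCF whose
  host flank falls below `minSegmentGenes` is absorbed into its neighbour
  during painting and so degrades to an EEJ call — the same ambiguity the
  underlying signatures have when read from a dot plot.
* **Ancestor reconstruction**: blocks at the WGD age (gate +/- 0.2 Ks)
  seed a single-linkage clustering in which the two sides of a block
  always merge, same-chromosome regions merge when they overlap by >= 5
  ranks, and abutting regions merge when they collinearise against the
  same partner chromosome — the latter rule is what keeps a nested
  insertion (which splits both copies at the same spot) from splitting a
  proto-chromosome in two. Validation requires each proto to appear
  exactly `multiplicity` times and, when outgroup blocks are supplied,
  one-to-one collinearity over >= 0.6 of its genes.
* **CSO logic**: admission requires presence in >= 8 subgenome units and
  in every required outgroup; categories are Absent/Single/Two/Multiple as
  a pure function of the count; clusters 1/2/3 key to the first outgroup's
  copy number (1, 2, >= 3); "present in over 50% of the subgenome" is read
  as a strict majority (> 0.5, i.e. >= 5 of 8 units); subgenome asymmetry
  is tested with a two-sided Wilcoxon signed-rank over species pairs
  (skipped below 5 pairs).
* **Duplication modes**: precedence WGD > TD > PD > TRD > DSD per gene;
  the TRD test asks whether the gene itself is absent from, but one of its
  homologs present in, the outgroup-anchored collinear set.

## Problem sizes

The bundled analyses run on simulated genomes of 11 chromosomes x 100–200
genes (2,200–4,400 genes per genome before polyploidy), with 50-scenario
rearrangement batteries, 20-replicate polarity batteries, and 500 planted
duplication events; mixture fitting uses 1,500 points per component. These
sizes were chosen so that every stochastic recovery statement is computed
from hundreds of independent draws while a full run stays at desk scale.

## Known limitations

* Depth ratios are reported as raw modal depths (6:3, not 2:1); reduction
  is the caller's interpretation step.
* The event classifier assumes each extant chromosome's signature is
  generated by fusions among distinct chromosomes; stacked rearrangements
  on one chromosome (e.g. an RTA landing on a previously fused
  chromosome) can corrupt a signature into UNRESOLVED or an adjacent
  category, which is surfaced rather than repaired.
* `sharedEventTest` matches events by age proximity; two genuinely
  independent events closer than the tolerance are indistinguishable
  without a third genome.
* NG86 with Jukes–Cantor correction saturates near Ks 3; peaks older than
  the ceiling are invisible to the mixture by design.
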