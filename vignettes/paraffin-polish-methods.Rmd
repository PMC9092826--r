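---
title: "Methods: combinatorial and classifier-based refinement of FFPE somatic SNV calls"
author: "ParaffinPolish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial and classifier-based refinement of FFPE somatic SNV calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Formalin fixation damages DNA: cytosine deamination produces uracil lesions
that sequencing reads as `C>T` (or `G>A` on the opposite strand),
fragmentation shortens insert sizes, and crosslinks degrade base qualities.
Somatic SNV callers run on FFPE tumour genomes therefore emit large numbers
of low-allele-fraction artifact calls alongside the real variants. There is
no orthogonal FFPE truth to tune against; what usually exists, in research
cohorts, is a matched fresh-frozen (FF) tumour from the same patient.

ParaffinPolish implements two refinement strategies against a composite FF
reference, plus the simulator used to validate both.

## The estimated metrics

Let `T` be the tested FFPE call set and `FF1`, `FF2` the somatic call sets
of two callers run on the matched FF tumour. We score

* `recall_est = |T ∩ (FF1 ∩ FF2)| / |FF1 ∩ FF2|`
* `precision_est = |T ∩ (FF1 ∪ FF2)| / |T|`
* `F1_est` = harmonic mean of the two.

The asymmetry is the point. A single FF caller's calls contain false
positives; scoring precision against the two-caller *intersection* would
misclassify an FFPE call confirmed by exactly one FF caller — a variant
seen in two of the three call sets involved — as wrong. Using the *union*
as the precision reference removes that failure mode while the
intersection keeps the recall target strict.

Undefined ratios (empty denominators) are reported as `NA`, never 0, so
"made no calls" and "all calls wrong" stay distinguishable; cohort medians
drop `NA`s. Cohort summaries are medians of per-sample metrics, not
metrics of pooled variants, so large samples do not dominate.

Variant identity is exact match on `(contig, pos, ref, alt)` after
optional contig-dialect normalization. SNV-only scope makes exact keying
adequate and fully deterministic; indels, MNVs and symbolic alleles are
dropped with a reported count. `FILTER`-failed records are excluded by
default (`pass_only = TRUE`), since callers' own filters are part of their
advertised output.

## The combinatorial search

Three call sets partition their union into 7 disjoint Venn regions in the
fixed order `A_only, B_only, C_only, AB, AC, BC, ABC`; a *region mask* is
an integer in 1..127 whose bit *i* selects region *i*. The fixed order and
bit convention are this package's choice, made so mask identifiers are
stable across runs; callers within a trio are taken in sorted label order
so each trio has one canonical partition. All C(n,3) trios of n callers
are enumerated in lexicographic label order.

Per-mask metrics are computed by a region-count decomposition: the regions
are disjoint, so a mask's call-set size and its overlaps with the strict
and broad truths are sums of per-region counts. The test suite re-derives
every row with plain per-key set arithmetic — a genuinely independent
route — and requires exact equality.

The "at least two" consensus rule (keep a variant called by ≥ t of k
callers, default t = 2) is provided for comparison; for k = 3 and t = 2 it
equals the mask selecting `{AB, AC, BC, ABC}`, and the tests assert that
identity. `bestBy` reports *all* argmax ties rather than an arbitrary
winner, because with small cohorts ties are common and hiding them would
overstate certainty.

## The 31 pileup features

Each candidate SNV is summarized from the tumour BAM alone (no matched
normal) by exactly 31 features in three categories:

* **summary (3):** `site_depth` (retained reads overlapping the position,
  including reads with a deletion spanning it), `tumour_vaf`
  (`var / (ref + var)`, 0 when both are 0), `other_alleles_fraction`;
* **per-allele counts and averages (14 × {ref, var}):** read count,
  plus/minus-strand counts, mean base quality at the site, mean mapping
  quality, mean position-in-read fraction (in read orientation), mean
  mismatch count as a fraction of aligned length (from `NM`), mean summed
  base quality at mismatched positions (from `MD`; for variant reads this
  includes the variant base itself, so "high-quality mismatches" flags
  artifacts), Q2-run statistics, mean clipped length, mean distance to the
  effective 3′ end, mean fragment length (|TLEN|), properly-paired
  fraction.

Conventions fixed here (and frozen so retraining stays consistent):
duplicates, secondary, supplementary, QC-fail and unmapped reads are
always excluded; base/mapping-quality floors default to 0; overlapping
mates count as two observations (read-based, as in readcount-style tools);
a "Q2 run" is a trailing segment of phred ≤ 2 bases in read orientation,
with distance measured from the variant base to the run start (0 when
absent); the "effective 3′ end" is the 3′ terminus after clip removal;
averages over an allele with zero supporting reads are imputed to 0, so no
feature is ever undefined. Input that is accepted as tumour-only keeps the
schema applicable to both tumour-only and tumour-normal calling setups.

## The classifier

Labels come from the FF truth: an FFPE call is positive iff its key is in
the strict (intersection) set. Features are standardized to zero mean and
unit variance with parameters frozen into the model — required for the
coefficient magnitudes to be comparable, which is how feature importance
is read; constant features get scale 1 and contribute nothing.

Training is a grid search over penalty ∈ {L1, L2} and 13 log-spaced
inverse-regularization strengths C ∈ [1e−3, 1e3] (glmnet's λ = 1/(nC)),
scored by mean F1 of the positive class over stratified, seeded
cross-validation folds (10 by default), with inverse-frequency class
weights on by default because artifacts heavily outnumber real variants in
FFPE call sets. Ties prefer stronger regularization, then L2 — the more
conservative model. The winner is refit on all data. With the same data
and seed the whole procedure is reproducible (coordinate-descent tolerance
1e−9); on near-separable data the weakest penalties may stop at glmnet's
iteration cap, in which case glmnet clamps to the smallest converged λ,
deterministically. The decision threshold defaults to 0.5 and is exposed
everywhere.

Leave-one-sample-out validation holds out all variants of one sample,
trains on the rest, filters the held-out calls and scores the kept set
with the estimated metrics; unfiltered metrics are reported alongside.
Models serialize to versioned JSON (schema, feature names, center/scale,
coefficients, hyperparameters, seed) so they are portable.

## The simulator

The simulator's defaults are the package's study conditions: a 50 kb
uniform-composition contig at 50× coverage (typical FFPE whole-genome
depth), 100 bp paired-end reads with 250 ± 30 bp fragments, 60 true
somatic SNVs with VAFs uniform in 0.15–0.6 (moderate purity/clonality), 2
deamination artifacts per kb restricted to C/G reference bases with alt
T/A and VAFs in 0.02–0.12, a 12-phred base-quality penalty and 0.6
fragment-length shrink on artifact-carrying molecules (re-centred so the
damaged base stays covered), and a 0.002 uniform base-error rate.
Allele assignment is per *molecule* (both mates agree), and `NM`/`MD`
tags are computed exactly so mismatch features work.

Five FFPE caller profiles span the space the method needs: a precise
low-pickup caller (sensitivity 0.85, artifact pickup 0.05, 20 private
FPs/Mb) through sensitive artifact-prone ones (up to 0.95 / 0.50 / 50),
plus two FF callers (0.92 and 0.95 sensitivity, 10 FPs/Mb, no artifact
pickup) whose sets overlap but differ, so the strict truth is a proper
subset of the broad truth and the recall/precision asymmetry is exercised.
These values are fixed design choices intended to emulate the qualitative
ordering real callers show (a precision-oriented caller, a
sensitivity-oriented caller, middling ones); they were set once from that
rationale.

What the simulator deliberately does not model: instrument-specific error
profiles, indel errors, subclonal structure, copy number, mappability and
alignment ambiguity (all reads are 100M at MAPQ 60), crosslink/abasic
artifact classes, and Q2 trailing runs (those features are exercised by
hand-built read fixtures instead). Passing tests therefore demonstrate
correctness of the algorithms and the expected qualitative behaviour on
deamination-dominated damage — not performance on real FFPE genomes, where
feature distributions are messier and retraining on labelled data is
expected.

## Numerical and design choices

* Seeds: one master seed fully determines a simulation; per-stage and
  per-sample seeds are derived arithmetically (kept under 2³¹) so stages
  are independently reproducible.
* Positions are 1-based throughout, as in VCF; no coordinate conversion.
* Writing a filtered VCF copies the template's record lines byte-for-byte
  (plus one provenance header line), preserving caller annotations.
* Degenerate inputs: empty call sets and empty truths flow through as
  `NA` metrics; training refuses single-class labels and n < folds;
  prediction refuses schema mismatches, listing the offending columns.
* Test and experiment sizes (15–50 kb contigs, 2–6 samples) were chosen as
  the smallest scales at which the binomial/Poisson checks and the
  end-to-end experiment are statistically comfortable.

## Known limitations

Exact-key matching ignores representational equivalence that haplotype-
aware comparison would catch (irrelevant for SNVs after normalization, by
design). The feature schema is tumour-only; matched-normal features would
likely help and can be added by retraining with an extended matrix. The
estimated metrics inherit the biology of the FF/FFPE comparison: the two
tissue blocks may genuinely differ, so even a perfect FFPE call set need
not reach recall_est or precision_est of 1 on real data.
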