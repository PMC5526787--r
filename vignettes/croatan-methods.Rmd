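---
title: "Guide selection, pairing and screen analysis: models and design choices"
author: "croatan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide selection, pairing and screen analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(croatan)
```

## Overview

`croatan` scores candidate SpCas9 knockout targets and designs dual-sgRNA
constructs. A guide's final 1–9 score combines three components:

1. **Potency forests.** Two stringency ladders of random forests, one per
   efficacy training dataset (a FACS-depletion-style "tiling" dataset and a
   mutation-rate-style dataset). A target passes rung *k* of a ladder if
   the forest trained with false-positive penalty *k* calls it potent; its
   per-ladder score is the highest rung passed, and the combined forest
   score is the minimum of the two ladder scores — a target must convince
   both ladders.
2. **Frameshift likelihood.** A linear model of microhomology-guided
   repair predicts the relative likelihood of each deletion that short
   flanking repeats can template at the cut. The frameshift (FSM)
   likelihood is the fraction of total predicted likelihood carried by
   deletions whose length is not divisible by 3. A guide passes the FSM
   test when this fraction strictly exceeds 0.66 *and* homology-guided
   repair is plausible at all at its site (the site's likelihood sum
   reaches a background-median cutoff).
3. **Conservation.** The mean absolute per-residue deleteriousness
   (PROVEAN convention, supplied as input) in a ±2 amino-acid window
   around the codon containing the cut; a guide passes when its score
   strictly exceeds the median over a background of coding-sequence
   sites.

The consolidated score is `3 * g + tests_passed + 1`, with `g = 0, 1, 2`
for forest-score groups A (1–3), B (4–6) and C (7–10) and
`tests_passed` the number of the two tests passed, so scores span 1–9
and group membership always dominates test outcomes.

## Cut-site geometry and coordinates

All coordinates are 0-based half-open; a cut coordinate is the boundary
index between two bases. SpCas9 cuts bluntly 3 bp 5′ of the NGG PAM,
between protospacer bases 17 and 18. The 30-nt feature context is 4 nt of
upstream flank, the 20-nt protospacer and 6 nt of downstream flank (the
PAM is the first 3 of the 6); within it the cut boundary sits at offset
21. The boundary convention makes the inter-DSB distance of a guide pair
`|cut_a − cut_b|` exactly, so divisibility-by-3 tests in pair scoring are
unambiguous. Sites whose 30-nt window runs off the sequence or contains an
ambiguity code are skipped; targets overlapping splice junctions are
likewise skipped because the context is taken from one contiguous genomic
window.

## Potency forests

Each 30-nt context is decomposed into its 28 overlapping 3mers,
position-specifically. The forests consume a one-hot design matrix
(28 positions × 64 possible 3mers = 1792 indicators; a bag-of-3mers
alternative with 64 count columns is available through
`featureMode = "bag"`). An earlier encoding that passed the 28 positions
as categorical predictors ordered by the response was rejected because
response-ordering of high-cardinality factors leaks the labels into the
features at these sample sizes — a shuffled-label control showed strongly
inflated out-of-bag correlations. With the one-hot encoding the shuffled
control is null, which the test suite verifies.

Training guides are labelled within gene: efficacy percentiles use the
midpoint convention `100 * (rank − 0.5) / n`, guides at or above the 60th
percentile are potent, at or below the 40th weak, and the middle fifth is
discarded. Percentiles are computed per gene for both datasets (a global
switch is available): within-gene ranking is what the percentile scale
means in the tiling dataset, and applying the same convention to the
mutation-rate dataset keeps the two ladders comparable.

The penalty ladder 0.2, 0.4, …, 2 is implemented as the class weight on
the weak class, so a false positive (weak called potent) costs *k* times
a false negative in the split criterion; prediction is a plain majority
vote over trees. Vote ties (possible with an even tree count) are broken
toward *weak* — deterministically and on the stringent side. No monotone
closure is imposed across the ladder: the per-dataset score is the
maximum rung calling potent even if a lower rung abstains. The class
default of 1000 trees per forest mirrors conventional practice; the test
suite and simulations use 60–150 trees, which is ample for the fixture
sizes involved and keeps the default test run fast. All training
randomness derives from a recorded seed (default 17); retraining with
the same seed reproduces predictions bit-exactly, as does a
serialization round-trip.

## Microhomology model

`enumerateMicrohomologies()` reports every maximal exact repeat with one
copy ending at or before the cut and one beginning at or after it, both
copies within a search window of the cut. Resolving a break through a
pair deletes the intervening sequence plus one copy, so
`deletion_length = dist_upstream + dist_downstream + length`. Sub-repeats
of a longer repeat with the same copy alignment are suppressed;
maximality is judged under the constraints (a repeat that could only be
extended across the cut is still maximal). Defaults — minimum homology
2 nt, window 30 nt per side — follow published microhomology-mediated
end-joining analyses and are exposed as arguments.

The resolution model is ordinary least squares of observed resolution
frequency on homology length, GC fraction and distance to the DSB. The
single distance covariate is the *sum* of the two flank distances
(a `"min"` mode is provided); frequencies are fitted untransformed, and
negative predictions are clamped to zero before normalization since the
model has no link function and likelihoods cannot be negative. Fitting on
log frequencies is a plausible alternative the data format permits; raw
frequencies are the default because the planted-truth generator and the
parameter-recovery tests are defined on that scale. Blunt end-joining
resolutions are outside the model: a site whose likelihood sum falls
below the HEJ cutoff simply fails the FSM test rather than falling back
to a template-free model, and when no pair scores above zero the FSM
likelihood is undefined and the test fails.

## Conservation

Conservation profiles are consumed, never computed: the package reads
per-residue deleteriousness tables and is agnostic to whether they are
substitution- or deletion-type scores. The score is the windowed mean of
absolute values with a ±2-residue flank (configurable), truncated at
protein ends; this windowed-mean form is a reconstruction, documented as
such. Non-coding cuts get an undefined score and fail the conservation
test instead of erroring the pipeline, so intergenic and intronic sites
flow through scoring with group membership intact.

## Pair scoring and matching

For each gene the top 20 consolidated-score guides are reranked by
off-target risk (ascending risk, then descending score; the default risk
is the count of exact genomic occurrences of the guide's 3′ 12-nt seed
followed by NGG, and the scorer is pluggable) and the top 10 enter a
10 × 10 pair matrix. Rules, in order: overlapping target intervals score
a terminal 0; pairs under 10 kb apart with an inter-DSB distance not
divisible by 3 and a shared transcript score a base 2.5; a +1 increment
applies when one guide scores below 7 and the other above 7 (a guide at
exactly 7 can never be imbalanced). Pairs that miss the base condition
but are imbalanced still carry the +1 — the rules apply sequentially.
"Targeting the same transcripts" is operationalized as a non-empty
intersection of the transcript sets covering the two cuts, and the
frame condition lives inside the 2.5 rule rather than as a separate
increment; no separate same-exon bonus is implemented because its value
is not recoverable.

Construct selection maximizes the total pair score over disjoint pairs.
The matcher is an exact dynamic program over vertex subsets — for slate
sizes (≤ 22 vertices) this is instant and provably optimal on general
graphs, which greedy pairing is not; the test suite checks it against
brute-force enumeration of all 945 perfect matchings of 10 guides. Ties
prefer pairing over leaving guides unmatched (weights are non-negative
and a full slate should yield 5 constructs even through zero-score
edges), then the lexicographically earliest partner. The
higher-scoring guide of each pair takes the human-U6 position (ties by
id); barcodes come from a pool with a configurable minimum pairwise
Hamming distance (default 3). Combinatorial mode simply crosses a guide
set against itself in both promoter positions, n² ordered pairs
including self-pairs.

## Screen analysis

Counts enter as a construct × sample table with reference and final
timepoints per replicate. Constructs with fewer than 50 reference reads
in a replicate are dropped from that replicate. Counts are scaled to
counts-per-million within sample ("none" is available), and
`LFC = log2((cpm_final + 1)/(cpm_reference + 1))` per replicate, then
averaged across replicates; z-scores standardize within replicate by
default (per-screen is available, and the configured order is recorded
in the result metadata). Because pooled sequencing measures relative
abundance, a screen where many constructs deplete shifts every LFC by the
change in library composition; `centerOn` therefore re-references each
replicate's LFCs to the median of a caller-chosen control set (the
non-essential-gene constructs, in the simulated screens). Gene-level hits
at stringency *q* require at least 2 of a gene's constructs inside the
most-depleted *q*% of all constructs; with essential genes as true
positives and non-essential genes as true negatives this yields TPR and
FPR per stringency (10–50%). P-values from the rank-sum, Friedman and
Spearman tests are reported raw, with a Benjamini–Hochberg column
available but never gating.

## Scar classification

Alignments against the amplicon are read from SAM/BAM; only CIGAR
insertion and deletion operations count as edits (mismatches and soft
clips are ignored). Mates sharing a query name merge into one fragment;
if one mate shows an edit inside a region the other mate covers without
showing it, the fragment is discordant and excluded — conservative
counting. A deletion running from the hU6-cut window through the cU6-cut
window is a fragment deletion, subclassified DSB–DSB only when its
endpoints equal the two cut coordinates exactly and the fragment carries
no other edit; otherwise edits are attributed to the cut whose ±5-nt
window (configurable; no published value exists) they touch, giving
h-indel, c-indel or dual-indel calls, and edits outside both windows are
counted as diagnostics without affecting the call. Fragments, not reads,
are the counting unit.

## Synthetic fixtures

Every input has a seed-deterministic generator with planted truth:

* **Genome**: non-overlapping two-exon genes alternating strands, CDS
  divisible by 3 with no internal stops, ≥ 20 NGG sites per locus.
* **Efficacy**: latent potency = 2 × protospacer GC fraction + 1 ×
  presence of a favorable 3mer planted into 30% of guides at a fixed
  context position, plus gaussian noise (σ = 0.15); these weights make
  the planted rule explain most of the variance while leaving realistic
  overlap between classes.
* **Resolutions**: frequencies from known coefficients (0.1 intercept,
  0.05/length, 0.3/GC, −0.01/distance) plus σ = 0.01 noise at n = 500.
* **Screens**: negative-binomial counts (dispersion 0.05, depth 1000×)
  over 3 replicates; essential-gene constructs deplete by δ = −2 log2
  units; library of 20 essential and 20 non-essential genes at 5
  constructs each.
* **Scars**: 300-bp amplicon, cuts at 100 and 200, read pairs covering
  the full amplicon with construction-exact CIGARs. The class
  composition is allocated exactly (largest-remainder rounding) because
  the mixture *is* the planted parameter; only the order is sampled.

What these fixtures do not emulate: sequencing error, alignment
ambiguity, guide-specific off-target toxicity, chromatin effects on
cutting, or real nucleotide composition. Passing tests demonstrate that
the algorithms recover what they model, on data generated under the
model's assumptions — not that the trained fixtures transfer to real
genomes, which requires the original training datasets.

## Problem sizes and numerical choices

The test suite trains 10-forest ladders at 60–150 trees on 300–400
guides, enumerates matchings for 10-guide slates against brute force,
simulates 2000-fragment scar libraries and 200-construct screens. The
exact matcher refuses more than 22 vertices; quantile thresholds in hit
calling use R's default type-7 quantile; percentiles use midpoint ranks
with average ties throughout; the FSM and conservation thresholds are
strict inequalities, so a score exactly at threshold fails.

## Known limitations

The published forests are not reproducible without the original training
tables, so forest quality is validated on planted-signal fixtures only.
The conservation score formula and the group band edges are
reconstructions of partially specified procedures (bands default to
A = 1–3, B = 4–6, C = 7–10 and are configurable, recorded in output
metadata). The off-target reranker is an exact seed+PAM counter, not a
full mismatch-aware scorer. Cross-gene pair scoring in combinatorial
mode carries a user-chosen constant weight rather than the within-gene
heuristics.
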