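---
title: "Functional grouping of transcript isoforms: model and methods"
author: "SFPGtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional grouping of transcript isoforms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SFPGtools)
```

## Motivation and model

Gene-level RNA-Seq analysis sums reads over all isoforms of a locus;
transcript-level analysis keeps every isoform separate. Neither captures
that distinct transcripts — from one gene via splicing, or from paralogous
genes — can encode proteins with the same function. SFPGtools groups
protein-coding transcripts by *predicted functional similarity of their
proteins* and recomputes expression per group.

Functional similarity is predicted from what is reliably available at
proteome scale: the primary sequence (via pairwise alignment) and
predicted domain/motif architecture (via an ensemble of InterPro
analyses). The underlying assumption — similar primary sequence plus
similar ordered secondary-structure elements imply similar function — is
well supported by homolog and paralog studies, but it is an
approximation: point mutations that change conformation without moving
the alignment, and context effects such as molecular crowding, are
invisible to it.

## The pair confidence scores

For each aligned protein pair the package computes two scores, both
clamped to [0, 100].

**Alignment components.** From the BLAST tabular fields and the catalog
sequence lengths, with scheme weights $w_{id} > 0$, $w_{cov}$,
$w_{gap} \le 0$:

$$AIS = w_{id} \cdot \frac{pident}{100},\qquad
  ACS = \frac{w_{cov}}{100}\sum_{i \in \{a,b\}}
        \Big(100 - 100\,\frac{len_i}{aln}\Big),\qquad
  AGS = gaps \cdot \frac{w_{gap}}{100}.$$

The coverage sum runs over the two sequences of the pair. A local
alignment much shorter than either sequence drives ACS strongly
negative; an alignment longer than a sequence (heavily gapped)
contributes a positive term. The latter is applied literally — such
pairs also pay the gap penalty, and the number of clamped scores is
reported so unusual inputs are visible.

**Discovery score.** $DS = \mathrm{clamp}\big((AIS+ACS+AGS)\cdot
100/w_{id}\big)$, the lenient score: local similarity alone can push a
pair over a cutoff, which makes DS suited to discovering novel partial
functional overlaps, at the price of over-prediction.

**Domain comparison.** Per InterPro analysis ("tool"), each protein's
signatures are ordered along the sequence (start, then stop, then
accession as a deterministic tie-break). A pair's per-tool label is the
strongest of:

- `STONM` — ordered lists identical (same type, order, number);
- `STNM` — identical as multisets (order lost);
- `STM` — identical distinct-signature sets (counts differ);
- `NM` — otherwise;
- `NP` — at least one protein has no prediction from that tool
  (including both empty: no evidence is not evidence of identity).

These five outcomes partition all list pairs; an exhaustive comparison
against a brute-force classifier over short signature lists is part of
the test suite.

**Knowledge score.** Non-NP labels contribute their per-tool weights,
$ITCS = \sum_{t:\,l_t \ne NP} w_t(l_t)$, and

$$KS = \mathrm{clamp}\Big((AIS+ACS+AGS+ITCS)\cdot
  \frac{100}{w_{id} + \sum_{t:\,l_t\ne NP} w_t(\mathrm{STONM})}\Big).$$

Skipping NP tools in both the sum and its maximum makes missing
predictions neutral — a pair is never penalized because a tool had
nothing to say. When *every* tool is NP there is no architecture evidence
at all and KS falls back to DS.

The denominator includes $w_{id}$ alongside the attainable non-NP
maximum. Normalizing by the maximum of the ITCS term alone would push
identical proteins above 100 and break the cutoff semantics (the cutoff
is defined on a 0–100 scale); normalizing the full numerator by its own
attainable maximum gives exactly 100 for identical sequences with
identical annotations, for *any* valid scheme. That identity bound, label
monotonicity (upgrading any one tool's label never lowers KS) and NP
neutrality are enforced as properties in the test suite, so they hold
regardless of the numeric weights chosen.

## The scoring scheme

The scheme is a configuration item (YAML or list), validated on load:
identity weight positive, gap weight non-positive, per-tool label weights
monotone STONM ≥ STNM ≥ STM ≥ NM. Defaults are implementation choices,
not canonical values: identity 100, coverage 50, gap −50, and per tool
STONM 10, STNM 6, STM 3, NM 0. With 14 tools and these defaults a
98%-identity, full-coverage, gap-free pair with four STONM tools scores
$KS = (98 + 40)\cdot 100/140 \approx 98.6$. All scientific conclusions
the package supports (the invariants above, group recovery on planted
data) are scheme-independent; absolute KS/DS values are not comparable
across schemes.

The default tool roster is the 14 member-database analyses of the
InterProScan 5.31–70.0 generation (CDD, Gene3D, HAMAP, PANTHER, Pfam,
PIRSF, PRINTS, ProDom, ProSitePatterns, ProSiteProfiles, SFLD, SMART,
SUPERFAMILY, TIGRFAM). Rosters drift across InterProScan releases, so the
roster is an argument everywhere; rows from unconfigured analyses are
ignored with a count.

## Group formation

At a confidence score cutoff CSC (a positive integer ≤ 100; default
KS ≥ 95), each transcript $t$ seeds the group
$\{t\} \cup \{u : score(t,u) \ge CSC\}$. Design choices:

- **Seed neighborhoods, not connected components.** Merging overlapping
  neighborhoods would chain distantly related proteins into
  false-positive groups and lose specialized functions; semi-overlapping
  groups are intended.
- **Singletons are materialized** so redistribution covers every kept
  transcript and per-sample totals are conserved.
- **Lower cutoffs admit false positives**: pair counts, total group size
  and maximum group size all grow as CSC decreases — the package asserts
  this monotonicity as an invariant rather than reproducing any
  particular proteome's counts, which depend on the annotation release.
- Duplicated member sets (every member of a clean family seeds the same
  set) can optionally be collapsed (`dedup`), keeping the
  lexicographically smallest seed; the default keeps one group per seed.

Pairs can also be classified by gene-name origin (same gene, same gene
family, different family, undefined). The family stem strips a trailing
`-NNN` transcript suffix, then either trailing digits (UBE2D1 → UBE2D) or
one trailing letter (HIST1H1A → HIST1H1). This is a deliberate
approximation chosen to reproduce well-known paralog series without an
external gene-family database; symbols that are bare numeric or
clone-style versioned accessions (e.g. `AC012345.1`) are uninformative
and classed undefined.

## Expression recalculation

Raw counts are made comparable across samples with median-of-ratios size
factors: the reference is the per-transcript geometric mean over samples
(log-space, using only transcripts positive in all samples), and each
sample's factor is the arithmetic median of its count/reference ratios.
If no transcript is positive everywhere the estimator stops with an
error (a pseudo-reference fallback is deliberately not implemented —
such matrices need a different design). The estimator agrees with
`DESeq2::estimateSizeFactorsForMatrix` up to that function's geometric
interpolation of even-length medians, and that agreement is asserted in
the tests.

Normalized counts are converted to FPKM with RSEM-style effective
lengths, $FPKM_{tj} = n_{tj}\,10^9/(L_t \sum_t n_{tj})$, where the
library size is the post-normalization column sum over transcripts with
$L_t > 0$. The library-size definition is a package choice: taking the
sum after normalization keeps the FPKM self-consistent with the
normalized counts it is derived from. Transcripts with effective length
0 (shorter than the fragment length; RSEM emits such rows) get FPKM 0
and leave the denominator, with a logged count. An all-zero sample
yields an all-zero column rather than a division error.

Group expression redistributes each member's FPKM over its groups:

- **ED (equal distribution)**: a member of $k$ groups contributes
  $FPKM/k$ to each — every group a member belongs to is equally
  important.
- **GD (group-size distribution, default)**: contributions are
  proportional to group size, $FPKM \cdot s_g / \sum_{h \ni m} s_h$ —
  bigger groups are favored, modeling genetic redundancy (heavily
  duplicated functions are the conserved, important ones).

Both rules distribute unit weight per member, so per sample the output
totals equal the transcript FPKM totals exactly (asserted to 1e-9
relative over randomized fixtures, typically exact to machine
precision). When all of a member's groups share one size GD degenerates
to ED. Excluded-biotype transcripts (nonsense-mediated decay —
degraded before translation; polymorphic pseudogenes — likely
non-functional; TR/IG genes — high mutual similarity but distinct target
affinities) never join groups yet pass through with their own FPKM.

Because group expression is derived from within-sample comparisons of
redistributed FPKM, SFPG values are meant for *relative* comparisons of
one group across conditions, not for ranking absolute expression among
different groups.

## Numerical choices

- Scores are clamped to [0, 100]; the number of clamped pairs is
  reported.
- The score formulas divide by the attainable maximum before
  multiplying by 100, so the identity bound (DS = KS = 100 for identical
  proteins) holds bit-exactly for arbitrary real-valued weights.
- Reciprocal BLAST hits and multiple HSPs are reduced to one record per
  unordered pair by maximal bit score, ties broken by lower e-value,
  higher identity, then first occurrence — deterministic and
  orientation-free. HSPs are not merged into composite coverage; the
  "number of gaps" is tabular column 6 (gap openings).
- Sequence lengths always come from the FASTA catalog (terminal stop
  stripped; an internal `*` is an error), never from BLAST columns.
- Degenerate inputs: empty exclusion sets, all-singleton group sets,
  pairs without any InterPro row (all-NP), transcripts missing from the
  annotation file (empty profiles) are all legal and covered by tests.

## The synthetic fixture generator

`makeFixture()` emits every input the pipeline consumes, deterministically
from a seed, with planted ground truth. It emulates:

- **Protein families** as mutants of a family root. Each member
  substitutes $k = \mathrm{round}((1 - id/100)L/2)$ positions drawn from
  disjoint position sets, so within-family pairs differ at exactly $2k$
  positions and hit the identity target (realized identities are written
  into the alignment rows). Between-family relatedness, when requested,
  comes from a shared ancestor, with member substitutions placed inside
  the family's own divergence positions so the between-family target is
  not eroded.
- **Domain architectures**: three signatures per annotated tool, shared
  within a family; perturbation plans downgrade one member in one tool to
  STNM/STM/NM/NP (order swap, duplication, replacement, drop).
- **Counts**: negative-binomial draws around lognormal baseline means
  (location log 500, scale 1), scaled by planted per-sample size factors,
  plus excluded-biotype decoy transcripts to exercise passthrough.

Default conditions — two families of five members at 98% within-family
identity and unrelated otherwise, four annotated tools, 300-aa roots,
three samples with size factors (0.5, 1, 2), NB dispersion 0.1, two NMD
decoys — are a deliberately clean, well-separated regime: realistic in
scale for a focused paralog neighborhood, chosen once as the reference
test conditions.

What the generator does *not* emulate: alignment statistics (e-values
and bit scores are filled but meaningless), indels (alignments are
gap-free and full-length, so coverage and gap terms are only exercised
by hand-constructed cases in the unit tests), overlapping or nested real
domain annotations, sequencing-depth artifacts, or any correlation
structure between expression and sequence similarity. Passing the
planted-recovery tests therefore demonstrates the machinery is correct
on separable inputs, not that any particular CSC is well calibrated for
a real proteome, where between-family similarity is continuous and
annotation quality varies.

Verification (`verifyAgainstTruth()`) demands exact recovery: every
non-singleton group equals the planted family of its seed. Its failure
modes are named — under-grouping when the cutoff exceeds the planted
similarity (e.g. CSC 100 against 98% identity yields all singletons) and
merged neighborhoods when between-family similarity approaches the
within-family target.

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen so the full suite completes
in about a minute: 1,000 random scheme/feature/label triples for the
scoring oracle, all signature-list pairs over a 3-letter alphabet up to
length 3 for the label tree, 20 seeded fixtures (10–11 proteins each)
for cutoff monotonicity, 100 fixtures for expression conservation, 2,000
transcripts for size-factor recovery, and a 10-protein two-family bundle
for the end-to-end command-line run.

## Known limitations

- The scoring-scheme weights are configuration, not canon; absolute
  scores from different schemes are not comparable, and no attempt is
  made to reproduce score values from any specific annotation release.
- Single best-HSP reduction under-estimates coverage for proteins whose
  similarity is split across several alignment blocks.
- The gene-family stem rule is heuristic; curated families
  (HGNC-style) would classify pair origins more faithfully.
- Grouping quality is bounded by the inputs: proteins missing from the
  BLAST output are never paired, and proteins without InterPro rows are
  scored on sequence evidence alone (all-NP fallback).
- Differential-expression testing, PCA/clustering and other downstream
  analyses are out of scope; the output matrix is designed to drop into
  those tools.
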