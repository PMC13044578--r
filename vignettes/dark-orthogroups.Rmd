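---
title: "Identifying conserved dark gene families: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying conserved dark gene families: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkog)
```

## The problem

In most non-model lineages a sizeable fraction of predicted proteins has no
ascribable function: every database hit is an "uncharacterized protein" or
similar, or there is no hit at all. These *dark* genes are frequently
taxonomically restricted and are plausible carriers of lineage-specific
biology (in stony corals, for example, stress response and
biomineralization). `darkog` implements a complete, testable pipeline for
finding gene families (orthogroups, OGs) that are dark yet well conserved
within a lineage, asking whether their restriction reflects true absence or
homology detection failure, and characterizing their expression and
remote-homology context.

## Darkness model

A protein is **light** if at least one homology hit with e-value at or
below the cutoff (default 1e-5) has a description containing *none* of the
ambiguous phrases; it is **dark** otherwise, including when it has no hits.
An OG is dark iff all its members are dark. Three matching decisions are
deliberately pinned, because database descriptions embed these phrases in
longer strings:

* matching is case-insensitive substring containment ("Hypothetical
  Protein ABC" is ambiguous);
* blank or whitespace-only descriptions are ambiguous — they carry no
  usable function;
* hits above the e-value cutoff are ignored entirely, so classification is
  reproducible from stored hit tables regardless of the search tool's
  reporting threshold.

The classification is monotone: informative below-cutoff hits can only move
a protein toward light, ambiguous hits can never flip a call.

## LCA assignment and the rank ladder

Each OG is assigned the most specific rank, on an ordered ladder of
taxonomic ranks, at which all member datasets carry the same non-missing
taxon. A dataset lacking a value at a rank cannot certify agreement there,
so the scan skips to the next rank — the conservative choice, since a
missing value is an absence of evidence. If no rank agrees, a flagged
root sentinel ("cellular organisms") is returned.

The ladder places the custom **suborder** rank (the Complex/Robust split of
stony corals) between `family` and `order`. Complex and Robust are clades
*inside* the order Scleractinia, so the suborder must be scanned before the
order: placed after it, an all-Robust OG would stop at
`order = Scleractinia` and the suborder could never be an LCA, and an OG
spanning both suborders could not resolve "above suborder, at order" as
intended.

## Conserved dark OG selection

Dark OGs restricted to one of the nested groups Scleractinia ⊆ Hexacorallia
⊆ Cnidaria qualify when their distinct member datasets cover at least 50%
of the narrowest group containing them (inclusive — 59 of 118 qualifies).
Using the narrowest group makes the three categories mutually exclusive and
exhaustive over selected OGs. Coverage counts distinct datasets, not
proteins, so paralog expansions do not inflate it. Any member outside the
widest group disqualifies the OG regardless of coverage.

Representative sequences are chosen by vote: an internal greedy centroid
clustering (candidates ordered by descending score-matrix row sum, cluster
membership by a score threshold) is run at several thresholds and each
run's centroids receive one vote; maximal votes win with lexicographic
tie-break, and ties are recorded. The clustering is a stand-in for external
re-clustering tools whose vote counts can also be supplied directly.

## Homology detection failure

The best bitscore between an OG's representative and each dataset is
modeled as exponential decay with patristic distance `d` (sum of branch
lengths on the species tree, measured from the representative's tip —
pinned, since averaging over member tips changes little but complicates
the anchor at `d = 0`):

$$B(d) = a\,e^{-b d} + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2)$$

The fit is nonlinear least squares (Levenberg–Marquardt, `a > 0`,
`b ≥ 0`, started from a log-linear regression), which handles both the
noiseless and the constant (`b = 0`) limits. A homolog is *detectable* when
its bitscore exceeds the Karlin–Altschul-style floor
`B_thr = log2(L_rep · L_db / E)` for e-value threshold `E`; the probability
of detection failure at distance `d*` is `P(B < B_thr)` under a Gaussian
predictive distribution whose variance is the residual variance plus
first-order (delta-method) propagation of the parameter covariance.

Numerical and interpretive choices:

* `E = 0` would put the floor at infinity, so the module requires
  `E > 0`; the default is 1e-3. (Search tools are sometimes driven with a
  literal 0 threshold, which we read as "report everything", not as a
  probability model.)
* The calibration requirement on the variance estimator is judged in the
  aggregate: over replicate fits, the mean predicted failure probability
  must match the mean Monte-Carlo failure frequency within ±0.03. A single
  fit carries estimation noise in the predicted mean, so per-fit agreement
  is only expected within that noise.
* Datasets absent from the OG but *inside* its LCA clade are scored and
  reported (their absence is more plausibly dataset incompleteness), but
  only datasets *outside* the LCA enter the OG-level call: HDF-supported
  when ≥ 50% of scored non-LCA datasets have `p > 0.95`, HDF-rejected when
  ≥ 50% have `p < 0.05` (support takes precedence on an exact tie),
  otherwise ambiguous; with nothing scorable the OG is flagged.

## Expression bias

All significance rules are strict inequalities, each pinned by a boundary
test: counts > 10 in > 10% of samples for the low-expression filter;
|log2FC| > 0.5 and padj < 0.05 for bulk DE; FC > 2.0 for single-cell
expression; |log2 FC| > 0.5 and Welch-test p < 0.05 for proteomics (log2 of
the ratio of arm means — the log2 reading is pinned but configurable; zero
variance in both arms with equal means gives p = 1 by convention).
Cross-version gene ids are mapped by reciprocal best hit with > 60% query
*or* subject coverage ("either" is the default reading of an ambiguous
rule; "both" is available), ties dropped.

The bias statistic is descriptive: per group (dark/light), the denominator
is the number of distinct group genes significant in ≥ 1 unit; per unit the
proportion is significant group genes over that denominator, and the bias
is `delta = prop_dark − prop_light`. A gene significant in k units counts k
times in numerators but once in the denominator, so proportions need not
sum to 1 across units. An optional two-proportion test is provided as an
extension, flagged as such.

## Remote-homology network

Hits are kept at probability ≥ 50% and query/subject coverage ≥ 60% (all
inclusive); a ≥ 90% preset exists because both thresholds are in
circulation for the same corpus, and the two presets are the only supported
readings. Edge weight is `score / alignment length`; per unordered OG pair
the single best-normalized-score hit survives (ties: higher probability,
then lexicographic query id), which also resolves query↔target redundancy.
The filter→normalize→deduplicate chain is idempotent and independent of
input row order. Components come from the graph library; tests check them
against an explicit breadth-first-search oracle.

## The synthetic corpus

The generator defines the study conditions under which every claim is
tested; its defaults are fixed once:

* **40 datasets** — 16 Scleractinia (8 Complex + 8 Robust), 12 further
  Hexacorallia, 8 further Cnidaria, 4 outgroups — on an ultrametric tree
  with crown depths 0.5 / 1.0 / 1.5 / 2.2 substitutions/site, giving
  within-group patristic distances up to ~1 and corpus-wide distances up
  to ~4.4, a realistic span for deep metazoan comparisons.
* **2000 families**, dark fraction 0.25 — enough dark families that the
  conserved subset (~170) is comparable in size to a real corpus's.
* Origin clades drawn with probabilities 0.35 / 0.25 / 0.15 / 0.15 / 0.10
  (single dataset / Scleractinia / Hexacorallia / Cnidaria / root), with
  per-branch loss 0.12 inside the origin clade.
* Bitscore decay: `a ~ U(150, 400)`; fast regime `b ~ U(1.2, 2.5)`, slow
  `b ~ U(0.05, 0.3)`, mixed 50/50; noise sd 10 bits (σ/a ≤ 0.07, within
  the regime where parameter recovery is expected). Fast families fall
  below the detection floor at inter-class distances, slow families do
  not, so the two regimes separate into HDF-supported and HDF-rejected.
* Cell-type enrichment: dark genes significant in "calicoblast" with
  probability 0.4 versus 0.1 for light genes; 0.15 elsewhere. Bulk DE uses
  0.15 (dark) versus 0.25 (light), reproducing the common observation that
  annotated genes dominate stress-response calls.
* Network: 3 hubs × 10 satellites planted above the filter thresholds
  (one edge exactly on them), with reciprocal duplicates, self-hits and
  sub-threshold decoys.

A single integer seed drives deterministic per-module substreams, so any
stage can be regenerated independently and byte-identically.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: no residues are evolved (bitscores and
descriptions are drawn directly from the planted model, so darkness
recovery is exact by construction rather than a statement about annotation
quality); absence is generated by clade-wise loss, not by assembly or gene
prediction artifacts; hit descriptions are deterministic given the planted
label; and the remote-homology table contains only the planted structure
plus decoys, not the dense near-threshold background of a real all-vs-all
comparison.

## Problem sizes and runtime

The test suite runs the oracle equivalences at 1000 random OGs (LCA),
500 random graphs (components), and 200 replicate fits (parameter
recovery), and the end-to-end acceptance run uses the default corpus of 40
datasets and 2000 families — sizes chosen so the entire suite completes in
about a minute on one CPU while keeping every statistical tolerance
meaningful.

## Known limitations

* The decay model assumes a single rate per family; rate variation across
  sites or branches is absorbed into the residual term.
* Wald confidence intervals from the nonlinear fit can undercover for
  small n or very low noise; the calibration property is therefore stated
  on the detection probability, not on interval coverage per se.
* The LCA scan trusts the lineage table; horizontally transferred or
  contaminant sequences will pull LCAs toward the root rather than being
  flagged.
* The proportion-bias statistic is descriptive and inherits the
  composition of the significant-gene denominators; it is not a
  differential-enrichment test.
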