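---
title: "Methods: longitudinal SAGE tag-count analysis with sagetime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal SAGE tag-count analysis with sagetime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagetime)
```

## The analysis problem

SuperSAGE quantifies a transcriptome as integer tag counts per gene and per
sequencing library. In an aging time course — here modeled on seven age
stages of *Podospora anserina* cultures sampled at days 6, 9, 10, 11, 12,
13 and 14 of growth — each gene yields a short count profile over
chronological age, one library per stage, without biological replicates at
the library level (individuals are pooled before sequencing). The package
implements the full analysis chain for such data: normalization,
reliability filtering, soft clustering of profile shapes, detection of
continuous age trends, GO over-representation with enrichment-map export,
and a permutation null for comparing gene lists across studies.

## Normalization, filtering, standardization

Counts are scaled to **tags per million** (tpm),
`tpm(g, t) = count(g, t) / library_total(t) * 1e6`, so libraries of
different depth are comparable. Library totals may exceed column sums
(unassigned tags); an optional per-stage scale-factor hook accepts external
library-bias corrections and defaults to 1. A stage value of zero means the
tag was not observed; profiles with more than 25% missing stages (with
seven stages: two or more) are removed. Whether a zero count or only a
file-level blank counts as "missing" is configurable; zero counts are the
default because SAGE has no explicit missing-value code. Before any
Euclidean-metric comparison, each profile `X` is standardized to
`(X - mean(X)) / sd(X)` with the sample (n−1) standard deviation — the
denominator is a package convention, fixed for reproducibility.
Zero-variance profiles cannot be standardized and are flagged instead of
transformed.

## Pairwise significance and the Audic–Claverie test

Downstream steps need a per-gene p-value for differential expression
between two libraries. The package uses the Audic–Claverie conditional
test, the standard exact test for two-library digital expression data:
given a count *x* in a library of *N₁* tags, the count *y* in an
independent library of *N₂* tags follows a negative-binomial law with size
*x* + 1 and success probability *N₁/(N₁+N₂)*. Two-sidedness is obtained by
doubling the smaller tail (each tail including the observed *y*) and
capping at 1 — stated explicitly because discrete two-sided p-values admit
several conventions. Tails are evaluated with `pnbinom()`, which is
log-scale stable for extreme counts; the test suite checks agreement with
direct summation of the conditional law to 1e−12. Fisher's exact test on
the 2×2 table of count versus library remainder is available as an
alternative. No multiple-testing correction enters any decision: the
pipeline applies fixed raw thresholds (1e−3 for stage-to-stage smoothing,
1e−10 for the endpoint filter), and Benjamini–Hochberg q-values are only
an optional extra column.

## Significance smoothing

Standardization erases scale, so a 1→3 tpm wobble would look like a
100→300 tpm regulation. Significance smoothing removes this over-fitting
risk before clustering: for each consecutive stage pair the
Audic–Claverie p-value is thresholded at 1e−3 (inclusive); stages joined
by non-significant pairs form maximal runs, and every value in a run is
replaced by the run's arithmetic mean. A fully significant profile is
untouched; a fully non-significant profile collapses to a constant and is
removed as change-free. The run-mean (segment) semantics was chosen over a
left-to-right cumulative running mean because only the run interpretation
makes fully non-significant profiles *exactly* flat, which the removal
rule requires; smoothing is idempotent and preserves each run's mean.
Smoothing operates on tpm values, before standardization, since
standardization is a prerequisite of the cluster metric rather than of the
significance logic. The genes surviving this step form the **cluster
profile library**.

## Fuzzy c-means and the Xie–Beni index

Profiles are clustered softly: fuzzy c-means assigns each profile a
membership in [0, 1] to every cluster (rows summing to 1), minimizing the
fuzzified within-cluster sum of squares under a Euclidean metric on
standardized profiles. The fuzzifier defaults to the classical *m* = 2;
*m* → 1 recovers crisp k-means. Centroids are initialized on k distinct
data rows chosen from the given seed with distance-weighted
(k-means++-style) sampling, which makes restarts reproducible and places
starting centroids in distinct dense regions; plain uniform row sampling
needs many more restarts to reach the same optima. Iterations stop when
the largest centroid movement falls below 1e−8 (or after 1000 iterations).
A profile that coincides with a centroid receives membership 1 there. The
cluster "core" reported for each cluster is the membership-weighted mean
profile, which is exactly the FCM centroid.

The number of clusters is selected by the **Xie–Beni index** — fuzzified
compactness divided by *n* times the minimal squared centroid separation;
smaller is better. `select_k()` runs several seeded restarts per candidate
k (default 2–12, 10 restarts), scores each k by its minimum index, and
returns the argmin with ties broken toward the smaller k. A partition
whose centroids coincide has undefined separation and is scored infinitely
bad rather than raising an error inside the sweep.

## Continuous trends

A gene is continuously regulated when its tpm profile correlates strongly
with chronological age — Pearson r against the literal day values
(6, 9, …, 14), not stage ranks — at |r| ≥ 0.7, the conventional cutoff for
strong linear correlation, **and** the first-versus-last-stage
differential-expression p-value is ≤ 1e−10. Correlation is computed on
unstandardized tpm; Pearson r is affine-invariant, so this choice is
cosmetic but fixed. Constant profiles have no defined correlation and are
labeled `none`.

## GO annotation, over-representation, enrichment maps

Annotations can be transferred from homology: every hit with E ≤ 1e−20
(inclusive) donates its subject's GO terms to the query gene. Term sets
are closed under `is_a`/`part_of` ancestry (the true-path rule) before
testing; closure includes the root by default — the root term then
annotates every annotated gene and can never look enriched, so including
it is harmless and keeps closure a genuine closure operator. Enrichment
uses the classic one-sided (upper-tail) hypergeometric test, unconditional
rather than an elim/conditional variant, with the universe restricted to
annotated genes inside the analyzed profile library (the GOstats default,
overridable to a whole-genome universe). Terms with p ≤ 0.01 (inclusive,
uncorrected) are reported. The enrichment map joins enriched terms of both
phenotypes (1 = up, 0 = down) with edges wherever the Jaccard coefficient
of their member-gene sets is ≥ 0.25 (inclusive); exports are the
four-column enrichment table, a GMT gene-set file and a GraphML graph. A
term enriched in both phenotypes keeps one node carrying its more
significant phenotype.

## The two-universe overlap null

To ask whether two down-regulated gene lists from different studies share
more genes than chance allows, the package draws, in each of 10,000
replicates, n₁ ids from universe 1 and n₂ ids from universe 2 (S ids
common to both universes) and records the intersection size. The shared
count S defaults to min(N₁, N₂) — the smaller transcriptome treated as a
subset of the larger, a reasonable default when the true intersection is
unreported; S is configurable. Closed-form moments (mean S·p with
p = (n₁/N₁)(n₂/N₂), and the exact variance from pairwise inclusion
probabilities) serve as an independent oracle for the simulation. The
observed overlap is standardized by the simulated mean and sample
standard deviation; z ≥ 3 (inclusive) is called significant, the 3-sigma
convention for an approximately normal null.

```{r overlap}
null <- simulate_overlap_null(N1 = 10059, n1 = 1202, N2 = 9704, n2 = 556,
                              reps = 10000, seed = 1)
null
overlap_zscore(89, null)
```

## What the synthetic generator emulates

`generate_tag_counts()` produces a ground-truth-labeled experiment with
the statistical structure the analysis assumes: eight planted profile
archetypes (three decreasing — early, late, terminal drop; three
increasing — early, late, steady; two transient peaks), per-gene
baselines from a log-normal abundance distribution, expected tpm closed
to one million per stage (tpm is compositional), and negative-binomial
counts. Defaults, chosen once as a realistic desk-scale rendition of a
SuperSAGE aging course and then frozen:

* seven stages at days 6, 9, 10, 11, 12, 13, 14, with libraries of ~400
  tags per gene (a 10⁴-gene transcriptome in ~4×10⁶-tag libraries) and
  ±15% stage-to-stage depth variation;
* archetype amplitude 10 (ten-fold regulation over the course), baselines
  log-normal around 60 tpm (sdlog 0.6);
* negative-binomial size 200 — mild overdispersion (~7% extra-Poisson
  CV), appropriate for single pooled libraries per stage where pooling
  has already averaged individual variation;
* an optional flat-gene pool (log-normal around 6 tpm) emulating the
  low-abundance, fluctuation-dominated profiles that significance
  smoothing exists to remove, and an optional dropout fraction (1–3
  zeroed stages) exercising the 25% filter.

Because tpm is relative, a "flat" gene is defined as constant on the
*closed* tpm scale: the archetype pool absorbs the compositional drift of
the ensemble and flat genes stay exactly flat in expectation. The
archetype templates were designed so that, after standardization, the
eight shapes are mutually well separated (minimum pairwise squared
distance ≈ 2.2) while every monotone template keeps |Pearson r| ≥ 0.76
with the day vector — both properties the recovery tests rely on.
`generate_annotations()` plants GO enrichment by sampling term members
with an odds multiplier on one archetype's genes (multiplier 1 = null);
`generate_blast_table()` emits 12-column tabular hits straddling the
1e−20 transfer cutoff.

What the generator does **not** emulate: tag-level sequence artifacts and
mapping ambiguity, vendor-specific library-bias corrections, correlated
gene modules beyond the planted archetypes, and real GO topology (the toy
ontology is a root, four categories and leaf terms). Passing recovery
tests therefore demonstrate that the chain is implemented correctly and
calibrated under its own assumptions, not that those assumptions hold for
any particular real dataset.

## Numerical and design choices

* Inclusive comparisons throughout: p ≤ 1e−3, p ≤ 0.01, E ≤ 1e−20,
  |r| ≥ 0.7, Jaccard ≥ 0.25, z ≥ 3.
* Ties in cluster-number selection go to the smaller k.
* FCM convergence is on centroid movement (tol 1e−8), not on the
  objective; the objective trace is retained and asserted non-increasing.
* Degenerate inputs are flagged, not fatal, wherever the pipeline can
  continue (zero-variance profiles, constant trends); they are hard
  errors where silent continuation would corrupt results (duplicate gene
  ids, ragged files, mismatched gene sets, k > n, degenerate nulls).
* Gene-to-cluster assignment for per-cluster gene lists uses argmax
  membership; a membership-threshold alternative is available through
  the membership matrix itself.
* Problem sizes in tests and examples (10³ genes, 10⁴ null replicates,
  10 selection restarts) are desk-scale renditions of the full design,
  chosen so the whole suite runs in minutes while keeping every
  statistical margin wide.

## Known limitations

The vendor statistics behind historical datasets of this kind are
unpublished; the Audic–Claverie test is a principled stand-in, so
per-gene p-values — and any count that thresholds them — will not
reproduce a specific study's gene tallies exactly. The smoothing
semantics ("mean of the previous and current non-significant values")
admits a cumulative-running-mean reading; the run-mean reading
implemented here is the one consistent with removing exactly the
change-free profiles. The two-universe overlap null treats the smaller
universe as nested in the larger unless told otherwise. GO enrichment
p-values are deliberately uncorrected, matching the fixed-threshold
convention of this analysis style; treat them as screening scores, not
calibrated error rates.
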