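---
title: "Copy-number variation regions and VST: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number variation regions and VST: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvst)
```

# The analysis

`cnvst` implements the population-differentiation arm of a read-depth CNV
study: two pig populations (a domestic breed and wild boars in the motivating
design, 24 + 6 animals) are resequenced, CNVs are called per sample from
normalized read depth (RD) with a CNVnator-style caller, and the package
takes it from there — filtering, merging into CNV regions (CNVRs),
copy-number genotyping, the VST statistic, top-percentile selection, and
annotation of the selected regions against gene and QTL intervals.

All internal coordinates are 1-based and fully inclusive (the CNVnator
convention); BED input/output is converted at the boundary. This matters
because the merge rule below is stated in whole base pairs: on inclusive
intervals "share at least 1 bp" is unambiguous, and `[100, 200]` versus
`[201, 300]` are adjacent, not overlapping.

## High-confidence call filtering

Four rules, all strict inequalities, applied per call
(`cnvFilterParams()` defaults):

* e-value `< 0.01` — the caller's significance for the depth deviation;
* deletion RD `< 0.7` and duplication RD `> 1.3` — a diploid region has
  RD near 1, a heterozygous deletion near 0.5, a single-copy gain near 1.5,
  so these cutoffs sit between the diploid mode and the first CNV states;
* length `> 1000` bp — short read-depth calls at 100-bp-bin resolution are
  unreliable.

Boundary values (RD exactly 0.7, length exactly 1000) are rejected; the
printed signs are strict and we follow them literally rather than offering a
strictness switch, so behaviour stays auditable. CNVnator prints four
e-value variants per call; the filter consumes the first (its primary
t-test value) by default, selectable by index since callers and versions
disagree on which column users consider canonical.

## CNVR construction

CNVRs are the connected components of the graph whose nodes are filtered
calls and whose edges join calls sharing at least one base. Components are
closed transitively (single linkage): a chain of pairwise-overlapping calls
is one CNVR even when its extremes do not touch. Each CNVR's interval is the
envelope of its component, which for a connected component is exactly the
contiguous union of its calls — so the implementation reduces the call set
with a zero minimum gap and the test suite checks it against a per-base-pair
occupancy bitmap oracle. A CNVR is `DEL` if all members are deletions, `DUP`
if all are duplications, `BOTH` otherwise; the mixed class is needed because
type-wise counts under-sum totals in published per-chromosome tables.

Per-population views are *re-merges* of that population's calls, not subsets
of the joint regions: removing one population's calls changes envelopes and
counts, which is how the two populations of a study legitimately end up with
different CNVR totals and size ranges.

Summaries follow the conventions of the field's tables: density is CNVR
count per Mb of chromosome; coverage is the base-pair union over the
chromosome length; the median of an even count is the mean of the central
pair; a chromosome without CNVRs reports 0 lengths with an explicit flag.

## Copy-number genotyping

The copy number of sample *s* in CNVR *r* is estimated from the call files
alone: `CN = 2 * mean RD` over the region, where bases covered by one of
*s*'s calls contribute the call RD (the mean RD where a sample's own calls
overlap) and uncovered bases contribute the diploid baseline 1.0. A sample
with no overlapping call is exactly diploid (2.0) — cells are never missing.
This is deliberately a transparent stand-in for a dedicated re-genotyping
step: it uses only what the caller reported, and its bias (shrinking CN
toward 2 where a call covers part of a region) is visible and testable.
Copy numbers are kept continuous by default; `roundCN = TRUE` is available
for sensitivity analysis.

The matrix lives in a `CNVRExperiment`, a `RangedSummarizedExperiment`
subclass whose rows are the CNVR ranges, whose single assay is `cn`, and
whose `colData` carries the population labels.

## The VST statistic

For each CNVR,

$$V_{ST} = \frac{V_{total} - (V_{pop1} N_1 + V_{pop2} N_2)/N}{V_{total}}$$

with `V` the copy-number variances and `N` the sample counts. VST is the
fraction of copy-number variance explained by the population split — the
copy-number analogue of FST. Conventions:

* **Variance denominator `N`** (population variance). Under it the
  sample-size-weighted within-group variances decompose the total sum of
  squares exactly, so VST is bounded by [0, 1] by construction. The formula
  as usually printed is silent on the convention; `N-1` is available as an
  option, and with it slight negative values can arise and are clamped (and
  flagged).
* **Degenerate regions**: `V_total = 0` means no copy-number variation and
  hence no differentiation signal; VST is defined as 0 and flagged rather
  than left 0/0.
* VST is invariant to relabeling the populations, to adding a constant to
  all copy numbers, and to rescaling; the suite asserts all three.

Top-fraction selection uses the nearest-rank quantile: for fraction *f* the
threshold is the VST value at rank `ceiling((1 - f) * M)` of the `M` sorted
values, and every record at or above the threshold is selected, ties
included. The published analyses report selections as "VST over a threshold",
which is a ties-inclusive rule; the exact quantile method is never stated,
and nearest-rank is the simplest order-statistic definition.

## Ordination and clustering

PCA is the singular value decomposition of the column-centered
sample-by-CNVR matrix; component *i* explains $d_i^2 / \sum d^2$. Signs are
fixed by making each component's largest-magnitude loading positive. The
sample tree is UPGMA (average linkage) on Euclidean copy-number distances —
an ultrametric display of sample similarity, standing in for
sequence-phylogeny tools whose role in the original design is a clustering
display, not an evolutionary inference. Samples are processed in
lexicographic id order so hierarchical-clustering ties break
deterministically.

## Annotation and enrichment

Gene/QTL annotation is interval overlap (at least 1 bp, mirroring the merge
rule; a minimum-Jaccard filter is optional) against user-supplied BED or
GFF3 files. Term enrichment is the standard hypergeometric
over-representation test with Benjamini–Hochberg adjustment across tested
terms; the universe defaults to every gene in the annotation map, the
closest analogue of web-service defaults. Terms with no selected gene are
skipped. Database content (GO/KEGG/AnimalQTLdb) is never fetched: inputs are
files, so runs are deterministic and offline.

# The synthetic study generator

`simParams()`/`simulateCnvData()` emulate the *input* side of the motivating
design so every stage is testable without external data: per-sample
CNVnator-dialect call files for 24 + 6 samples on the 18 pig autosomes
scaled to 2% of their true lengths (≈45 Mb, preserving relative chromosome
sizes so density/correlation summaries are exercised on the real length
structure), a manifest, a chromosome-sizes file, synthetic gene/QTL BEDs and
a gene-to-term map, plus truth tables for scoring.

Planted regions (defaults: 2250 shared + 21 differentiated, non-overlapping,
1.5–8 kb) carry integer copy-number states — single-copy changes (1 or 3)
for shared regions, homozygous deletion or double duplication (0 or 4) for
differentiated ones, where selection signals in livestock scans are
typically strong dosage changes. Carrier calls get RD `(CN/2) ·
exp(N(0, 0.05))` (multiplicative, matching read-depth behaviour), endpoints
jittered up to ±200 bp, e-values below 0.005. False positives arrive at 0.3
per Mb per sample with RD drawn from U(0.6, 0.8) ∪ U(1.25, 1.4) —
deliberately straddling the filter cutoffs so boundary behaviour is
observable — lengths down to 300 bp, and half their e-values above 0.01.

Carrier frequencies are the core modelling choice:

* Shared regions sit at mid-range frequencies (uniform 0.22–0.32), with the
  two population frequencies pushed apart by a bounded offset of magnitude
  0.15–0.45 (random sign, floor 0.04 in both populations). The offsets give
  the populations genome-wide divergence — which is what makes real
  populations separable on PCA and monophyletic on a UPGMA tree — while the
  bounds and the frequency floor guarantee no shared region is ever private
  to one population, keeping its VST well below the planted signal regions.
* Differentiated regions use carrier frequencies 0.9 versus 0.1.
* **Carrier counts are exact**: a region at frequency *f* in a population of
  *n* samples gets `round(f·n)` carriers, drawn uniformly at random. With
  only 6 samples in the second population, Bernoulli sampling would
  routinely realize planted frequencies far from their nominal values — a
  region planted as differentiated can realize as undifferentiated and vice
  versa — making recovery scoring against the truth labels ill-posed. The
  exact design keeps the truth classes true *in the generated sample*.

What the generator therefore does **not** emulate: population-level sampling
noise (real carrier counts are random), rare variants (real CNVR frequency
spectra are rare-skewed; the generator's shared regions are common so that
every region is informative for structure), linkage between regions, and
read-level artifacts (GC bias, mappability). Passing the recovery tests
shows the pipeline is correct and well-calibrated under known ground truth;
it does not show that 6 samples suffice to estimate population frequencies —
they do not, and on real data of this shape the top-percentile list will
contain sampling-driven entries that no method can distinguish from
selection signals.

Everything derives from one seed; the same seed reproduces byte-identical
files.

# Numerical and design notes

* Degenerate inputs: empty call files parse to empty sets; chromosomes
  without CNVRs are reported with zero counts and flagged medians; an
  all-degenerate VST table selects nothing, with a warning.
* `V_total ≤ 1e-12` is treated as zero variance; copy-number cells are
  non-negative by class validity.
* Region placement distributes planted regions across chromosomes
  proportionally to length and errors out (rather than silently overlapping)
  when they cannot fit with the minimum gap; the gap (1 kb) exceeds twice
  the boundary jitter so neighbouring planted regions can never merge.
* Problem sizes in the test suite: module tests run on toy fixtures and a
  reduced simulation (≈9 Mb genome, 186 regions); the acceptance-level
  recovery test runs the full default simulation across 10 seeds, which is
  the package's definition of the study-scale check.

# Known limitations

* The copy-number estimator inherits the caller's segmentation: a call that
  partially covers a CNVR dilutes its CN toward diploid in proportion to the
  uncovered fraction.
* VST with 6 samples in one population is coarse (its within-population
  variance has 6 terms); the package computes it faithfully but cannot
  repair the design imbalance.
* Exactly two populations are supported for VST, matching its two-group
  definition; multi-group generalizations are out of scope.
* GO/KEGG/QTL database semantics (DAG propagation, trait classes) are not
  modelled; enrichment is a flat hypergeometric test over a user-supplied
  map.
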