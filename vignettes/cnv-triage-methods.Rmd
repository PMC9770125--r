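---
title: "Methods: CNV prioritization, classification and cohort reporting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV prioritization, classification and cohort reporting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvtriage)
```

## The analytical model

`cnvtriage` operationalizes a standard clinical-genetics workflow for
array-derived copy-number data in a congenital heart disease (CHD) cohort.
Its central assumption is that raw segment calls decompose into three
populations: benign polymorphic CNVs shared with the general population
(covering on the order of 12% of the genome), small technical or
inconsequential calls, and a small residue of large, rare events from which
clinically reportable findings are drawn. The pipeline makes that
decomposition explicit and auditable.

All coordinates are **0-based, half-open** internally; 1-based inclusive
array exports are converted at the I/O boundary and the conversion is
self-inverse. Chromosome labels are normalized by stripping any `chr`
prefix. A single genome build is assumed across all inputs; no liftover is
performed.

## Filtering parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_size_bp` | 100,000 | bases | lower bound defining "large"; a single lower bound, no upper bound — very large events are observations, not exclusions |
| `max_control_frequency` | 0.001 | fraction | carrier frequency above which a matched control region disqualifies a call as "rare" |
| `reciprocal_overlap_threshold` | 0.5 | fraction | the field-standard criterion for two CNVs being the same event: `min(shared/len(a), shared/len(b))` |
| `require_type_match` | TRUE | — | deletions are only matched by control deletions, duplications by duplications |
| `min_probes` | 1 | probes | optional probe-support floor; calls lacking a probe count pass |

A call overlapping several control records is removed if **any** matching
record crosses both thresholds; this is deliberately conservative toward
rarity. Sample-level QC consumes an upstream `qc_pass` flag rather than
recomputing platform metrics (MAPD and the like are upstream of this
package), and additionally excludes samples whose sex-chromosome profile
implies aneuploidy, since the autosomal copy-number baseline of an aneuploid
genome is not the diploid one the classifier assumes.

## Karyotype inference

Mean X and Y copy numbers are rounded to the nearest integers; a deviation
greater than `tolerance` (default 0.3) on either chromosome yields the
ambiguous label `other`. The integer pairs (2,0), (1,1) and (2,1) map to
46,XX, 46,XY and 47,XXY; all other pairs to `other`. With Gaussian
measurement noise of σ = 0.1 the expected label accuracy is
(2Φ(3) − 1)² ≈ 99.5%, which the test suite verifies empirically on 10,000
simulated profiles.

## The classification rubric

The rubric is a deliberately reduced, fully deterministic realization of the
semiquantitative ACMG/ClinGen copy-number framework. Only the sections that
can be computed from the data at hand are automated:

* gene content (dosage-sensitive genes fully contained, disrupted, or
  present without an established dosage flag; gene-empty CNVs),
* control-population frequency (absent vs common at the run thresholds).

The literature/case-count and inheritance sections require curation outside
any call set (database review of similar patients, parental genotypes). They
enter through an optional **manual points adjustment** table, matched to
calls by sample, type and ≥ 50% reciprocal overlap, and recorded in the
evidence ledger under rule id `MANUAL` with a free-text justification. The
packaged cohort fixture uses three such adjustments to encode the expert
judgment that distinguishes, e.g., a recurrent-disease-region deletion from
an otherwise identical-scoring one. Every contribution is itemized;
`evidence_points` always equals the sum of the ledger items, and the
cut-point mapping (≥ 0.99 Pathogenic, ≥ 0.90 Likely pathogenic, the
symmetric negative cuts for the benign side) is monotone in points. The
cut-point comparison carries an epsilon of 1e-9 because point totals are
sums of decimal fractions.

Candidate genes are nominated by a strict conjunction: pLI ≥ 0.9 (the
conventional reading of "highly loss-of-function intolerant"), murine
developing-heart expression, and a cardiac or embryonic mouse-model
phenotype. Missing evidence is represented as `NA`, never as `FALSE`, and a
missing criterion fails the conjunction: "no evidence" is not "evidence
against", but it cannot support a nomination either. Nomination is monotone:
completing missing evidence can only add nominations.

## Call-level vs event-level accounting

Arrays sometimes fragment one biological duplication into adjacent
segments. The package counts **CNVs of interest on the call-level table**
as the array reported it (two adjacent duplicated segments hitting two genes
count twice), because that is how per-CNV tables are conventionally
enumerated, while **classification and patient-level yield are computed on
events** produced by `merge_adjacent()` (default `max_gap` = 50 kb,
same-type only), because pathogenicity judgment applies to the underlying
biological event. The default gap is a conservative, configurable knob; the
exact adjacency rule used by any given array pipeline belongs to its
upstream documentation. Merging is idempotent and verified against an O(n²)
union-find oracle.

Yield uses two denominators on purpose: the P/LP yield divides unique
carrier patients by the number of *CNV-analyzed* patients, whereas the total
discovery yield adds aneuploidy findings and divides by the number
*enrolled* — an aneuploid sample is excluded from CNV analysis yet is
plainly a reportable finding. Conflating the denominators silently shifts
the total yield. A patient contributes at most once to each numerator;
variants of uncertain significance never enter a numerator. Percentages are
rounded half-up to one decimal at presentation only.

## What the synthetic data emulates — and what it does not

`simulate_cohorts()` generates, from a single seed: disjoint benign
polymorphic regions covering 12% ± 2% of the autosomal toy genome with
carrier frequencies drawn log-uniformly in [0.005, 0.2] — decisively above
the 0.1% rarity cutoff, so every background call's expected fate is
unambiguous; per-case benign background calls at those frequencies; Poisson
sub-100 kb nuisance calls; and rare spiked CNVs placed (or validated, if
user-supplied) to avoid ≥ 50% same-type reciprocal overlap with any benign
region. A spike that collides with a same-type benign region is an error
because it would corrupt the ground truth. The truth table records each
spike's expected survival, known-gene status and candidate status.

`make_paper_fixture()` is the deterministic counterpart: 90 samples with
fixed demographics (50/40 female/male split, predominantly one ancestry
group, Tetralogy of Fallot the most frequent diagnosis), one 47,XXY
profile, thirteen described CNVs at band-consistent toy loci (the
duplicated 5q35 region split across two adjacent segments), 24 gene-desert
decoys spanning 100 kb to 6.1 Mb, benign background tied to the control
table, and the three manual adjustments. It is built without RNG, so
repeated calls — and therefore result bundles — are byte-identical.

The simulator emits segment calls, not probe-level intensities; it does not
model mosaicism, call fragmentation noise, breakpoint uncertainty, batch
effects, or ancestry-dependent control frequencies. Passing tests therefore
demonstrate the correctness of the filtering/interpretation logic under
idealized segmentation, not robustness to array artifacts.

The toy genome uses nine autosomes of 12–50 Mb plus X and Y with the eleven
genes of interest at band-consistent positions; gene placements, pLI values
and dosage flags are synthetic encodings of the genes' narrative roles, not
database records.

## Problem sizes and numerical choices

The test suite exercises: 1,000 random interval pairs against a
base-enumeration oracle on a 10 kb toy chromosome (plus an independent
interval-library cross-check); 1,000 random annotated CNVs against a
straight-line rule-sum oracle; 20 seeded 90-case cohorts with 10 spikes
each for cascade sensitivity (≥ 0.95) and benign leakage (≤ 0.05) — both
are exactly 1.0 and 0.0 under idealized segmentation, the thresholds leave
headroom for configuration changes; and 10,000 noisy karyotype profiles
(≥ 99% label recovery). These sizes keep the full suite around a minute on
one CPU while leaving the statistical checks well-powered.

Degenerate inputs are defined errors, not silent behavior: zero-length
intervals, negative copy-number means, carrier counts exceeding cohort
sizes, duplicate sample ids, empty cohorts in summary tables, and zero yield
denominators all raise located errors. Empty *tables* (no calls, no
controls, no curation) are valid and propagate to empty-but-well-formed
outputs.

## Known limitations

* The rubric automates only dosage, gene-count and frequency evidence;
  classifications requiring literature or database review are only as good
  as the supplied manual adjustments.
* Control matching treats the control resource as a single merged frequency
  table; heterogeneous source cohorts are not modeled separately.
* Copy-number states are treated as integer-like per call; mosaic fractions
  are out of scope.
* X/Y calls are exempt from the copy-number/type consistency check because
  the ploidy baseline depends on sample sex, which call tables do not carry.
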