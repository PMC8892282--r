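---
title: "Methods: surfaceome classification, endocytome profiling and target prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surfaceome classification, endocytome profiling and target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfaceomics)
```

# Scope and model

`surfaceomics` implements the computational side of a tumor-surfaceome
profiling workflow: cell-surface proteins are labeled, optionally allowed to
internalize (the *endocytome*), enriched, and quantified by label-free
LC-MS/MS. The package covers five analysis stages and a synthetic-data
module that makes all of them testable offline:

1. **Classifier construction.** A curated catalog of bona fide
   extracellularly exposed membrane proteins is merged from nine annotation
   sources (a machine-learning surfaceome predictor, three GO membership
   terms, and five reviewed UniProt topology/keyword exports), deduplicated
   ("filter A"), curated by an exclusion/addition list ("filter B"), and
   categorized by membrane topology.
2. **Abundance preprocessing.** Protein-level intensities are imputed for
   low-abundance dropout and normalized to equal total intensity per sample.
3. **Differential expression.** Per-protein log2 fold changes with Welch
   tests on log2 intensities, BH adjustment, and an inclusive
   ≥ 0.5-log2-FC up-regulation partition across the surface and endocytosed
   fractions.
4. **Enrichment.** A preranked gene-set enrichment statistic (weighted
   Kolmogorov–Smirnov running sum) with a label-permutation p-value, and
   hypergeometric pathway overrepresentation.
5. **Target prioritization.** Proteins identified in both fractions are
   ranked by abundance per fraction (lowest = 1), split into quadrants at
   the median rank, and the high-surface/high-endocytosis quadrant is
   prioritized — the profile an antibody–drug conjugate (ADC) or
   radioimmunotherapy target needs.

# Classifier construction

## Merging and curation

Sources are delivered as TSV exports with an `accession` column and optional
`symbol`, `tm_count` (annotated transmembrane segments) and `gpi_flag`
(GPI-anchor annotation) columns. Accessions are the canonical identifier;
gene symbols are labels only, because annotation exports mix the two
vocabularies and only accessions are unambiguous. Isoform suffixes
(`-<digits>`) are stripped on load: the catalog counts proteins, not
isoforms.

`merge_sources()` unions the catalogs into one record per accession.
Topology evidence is reconciled conservatively — maximum `tm_count`, logical
OR of `gpi_flag` — and symbol conflicts resolve by a fixed source-priority
order (the order of `source_tags()`), which keeps merges deterministic.

Curation is data, not code: the manual database/literature review that
removes false positives and adds missed proteins is represented as a
reviewable CSV of `exclude`/`add` rows with reason codes. An `always_keep`
set (typically the full predictor catalog, whose published accuracy
justifies retaining it wholesale) protects entries from exclusion;
overridden exclusions are reported rather than silently dropped.

## Topology categories

`categorize()` assigns exactly one of four categories with the precedence
GPI > multipass > single-pass > other:

* `GPI` — GPI-anchor annotation present, regardless of transmembrane count;
* `MULTIPASS` — ≥ 2 transmembrane segments;
* `SINGLE_PASS` — exactly 1;
* `OTHER` — no major topology evidence.

Mutual exclusivity makes the partition invariant (category counts sum to the
total) testable. Published surfaceome catalogs sometimes report per-category
counts that overlap slightly; when a fixture must realize a fixed total with
a fixed residual class, the generator keeps the GPI, single-pass and
residual counts and absorbs the remainder into the multipass class, the
largest category.

# Abundance preprocessing

## Low-abundance resampling imputation

Label-free LC-MS/MS dropout is missing-not-at-random: the probability a
protein is unquantified rises as its intensity falls. The imputation
therefore resamples from each sample's low-abundance tail: a missing cell is
replaced by $2^u$ with $u \sim \mathrm{Uniform}[\min_{\mathrm{obs}} - s,\; q]$,
where $\min_{\mathrm{obs}}$ is the sample's lowest observed log2 intensity,
$s$ is the floor shift (`impute_floor_shift`, default 1 log2 unit) and $q$
is the `impute_low_quantile` quantile (default 0.05) of the sample's
observed log2 intensities. The draws are seeded, observed cells are never
altered, and imputed cells never exceed the sample's low-abundance quantile
— both properties are asserted in the tests. Commercial pipelines implement
"low-abundance resampling" without publishing the algorithm; this seeded
uniform window realizes the same intent with a testable bound.

## Total-intensity normalization

`normalize_total()` scales every sample column to a common total — the
median of the column totals by default, which fixes the arbitrary constant
in a scale-stable way. Column totals agree to a relative tolerance of 1e-9
after scaling, and scaling preserves within-sample rank order.

Total normalization assumes the bulk of signal is unchanged between
samples. When a large share of total intensity is differential (as in a
small panel where half the proteins carry planted effects), the column
rescaling shifts every fold change by the log-ratio of totals. The analysis
scripts therefore simulate a realistic quantified proteome (2,000 proteins)
in which the differential classifier members are a small intensity share;
at that composition the planted up-regulation Venn survives normalization
exactly.

# Differential expression

Fold changes are differences of mean log2 intensities. Significance uses
Welch's unequal-variance t-test on log2 values — the standard choice for
label-free abundances, robust to variance heterogeneity — with BH-adjusted
q-values reported alongside raw p-values. Degenerate rows are handled
explicitly: zero variance in both groups gives p = 1 at equal means and the
smallest representable double (flagged) at unequal means; fewer than two
replicates per group yields fold changes with `NA` p-values rather than a
failure.

Welch's approximation is conservative at very small group sizes (empirical
size ≈ 0.03 at n = 3 per group); the null-calibration checks in the test
suite run at n = 10 per group over 1,500–2,000 simulated null proteins,
where the test is near-nominal, and assert the type-I error rate inside a
95% binomial confidence band around 0.05.

The up-regulation partition uses an **inclusive** cutoff (fold change
≥ 0.5 log2 counts as up-regulated) and classifies each protein as
surface-only, both, or endocytosed-only; a protein absent from one
fraction's fold-change map is not up-regulated there, rather than treated
as infinitely down.

`relative_abundance_to_min()` implements the per-protein normalization used
for cross-sample displays: each sample's abundance as log2 fold over the
protein's lowest-abundance sample, so every protein has a zero somewhere
and all values are nonnegative.

# Enrichment

## Preranked gene-set statistic

For a ranked list of $N$ proteins and a gene set with $N_h$ members, the
running sum gains $|r_i|^w / N_R$ at members ($N_R = \sum_{hits} |r_i|^w$)
and loses $1/(N - N_h)$ at non-members; the enrichment score is the value
of maximum absolute deviation, in $[-1, 1]$. The weight default is
$w = 1$; $w = 0$ recovers the classic Kolmogorov–Smirnov form, under which
the score is invariant to positive rescaling of the ranking scores. A gene
set spanning the whole list scores 1 by convention.

The permutation null shuffles set membership over list positions with the
scores held fixed (gene-label permutation — appropriate for preranked
inputs, where no per-sample phenotype labels exist to permute), and the
two-sided p-value uses the standard +1 pseudo-count,
$p = (1 + \#\{|ES_b| \ge |ES_{obs}|\})/(B + 1)$, so $p \ge 1/(B+1)$.
Defaults: 1,000 permutations, seeded. The implementation is cross-checked
in the tests against a position-by-position brute-force oracle and against
an independent implementation of the same statistic.

## Overrepresentation

Pathway overrepresentation is the one-sided hypergeometric upper tail
$P(X \ge k)$ for an overlap of $k$ between a query of size $n$ and a
pathway of size $K$ in a universe of $N$, BH-adjusted across pathways.
Pathways are intersected with the universe before testing, and the tests
verify the tail probability against exhaustive enumeration for small
universes.

# Endocytome ranking and prioritization

`overlap_partition()` is exact set algebra over the surface and endocytosed
identity sets. Shared proteins are ranked per fraction by abundance with
dense unique ranks (1 = lowest); ties break by ascending accession so each
axis is a strict permutation — a tied rank would make the quadrant split
ambiguous. Ranks depend only on order, so any strictly monotone transform
of the abundances leaves the result unchanged.

The quadrant boundary is the median rank (HIGH iff rank > ⌈n/2⌉) — the only
parameter-free reading of a four-quadrant rank plot. Within the prioritized
HIGH_HIGH quadrant, candidates are ordered by descending rank sum
(surface + endocytome), ties again by accession; the rank sum is a natural
scalarization when no within-quadrant ordering is otherwise specified.

# Synthetic data

The generators produce every input the pipeline consumes, with ground truth
sufficient to score each downstream stage.

**Annotation fixtures.** `simulate_annotation_sources()` builds a universe
in which the final classifier is the predictor set (default 2,886) plus the
curated additions (default 431). Non-predictor sources draw half their
records (configurable) from the predictor set and the rest from a
false-positive noise pool; all noise accessions that reach a source are
listed as curation exclusions, and additions enter only through the
curation list. Default source sizes (2,886 / 5,196 / 935 / 437 / 939 /
2,356 / 2,819 / 3,724 / 2,726) emulate a realistic nine-source merge.
Source tags are provenance only — the topology-named sources do not
preferentially sample proteins of their category, which the classifier
logic never relies on. `category_targets` plants transmembrane/GPI evidence
to force an exact composition. Accessions are synthetic (`SYN` + integer)
to avoid implying real proteins.

**Abundance experiments.** Log2 intensities are protein baseline
(global mean 20, protein-level SD 2 — a realistic dynamic range) plus
planted condition/fraction effects plus replicate noise (SD 0.3 by
default, matching typical label-free replicate CVs). Dropout follows a
logistic MNAR model on log2 intensity, by default centered 4 log2 units
below the global mean with slope 0.75, giving sparse low-abundance
missingness; it can be disabled. `partition_targets` plants a
surface-only/both/endocytosed-only up-regulation truth using Δ = 1.5 log2
against replicate SD 0.1 — a high signal-to-noise regime chosen so the
planted truth is exactly recoverable (the margin to the 0.5 cutoff is
≈ 12 standard errors, and null fold changes sit ≈ 6 standard errors below
it), making recount checks sharp rather than probabilistic. The
planted-effect *recovery* experiments instead use the harder published
regime Δ = 1.0, SD 0.3, n = 3, where sensitivity ≥ 0.9 and false-positive
rate ≤ 0.05 at the 0.5 cutoff are asserted statistically.

**Patient cohorts.** `simulate_patient_cohort()` gives each synthetic
patient a distinct planted hotspot subset over a shared panel, emulating
heterogeneous relative surfaceome abundance across tumors; hotspots are
recoverable from `relative_abundance_to_min()`.

What the generators do *not* emulate: peptide-level structure, shared
peptides, retention-time effects, batch effects, correlated protein
modules, or heavy-tailed contaminant distributions. Passing tests therefore
demonstrate the correctness of the analysis logic under the stated
statistical model, not robustness to every artifact of real LC-MS/MS data.

# Determinism and numerical choices

Every stochastic step (imputation, permutation, simulation) takes an
explicit seed; the pipeline driver fans one global seed into named
substreams so stages are independently reproducible, and reruns of
`run_profile()` with the same config are byte-identical on disk. Ranked
lists break score ties by ascending identifier; ranking axes break
abundance ties the same way; all cutoffs are inclusive as documented.
Degenerate inputs (empty intersections, all-missing samples, zero column
totals, empty gene sets) raise errors naming the offending sample or file
rather than propagating NaNs.

Problem sizes in the tests and analysis scripts (500–2,000 simulated
proteins, 1,000–2,000 null proteins for calibration, 200–1,000
permutations) were chosen as the smallest sizes at which the asserted
statistical properties are stable.

# Known limitations

* The curation step reproduces a manual review only as well as the supplied
  curation file; the package cannot re-derive literature judgments.
* "Low-abundance resampling" is realized as a seeded uniform window in the
  low tail; vendor implementations may differ in distribution shape.
* With a single replicate per group the differential stage reports fold
  changes only.
* Total-intensity normalization is compositional and can distort contrasts
  when a large intensity share is truly differential (see above).
* The enrichment module reports a single gene set per call; no
  multi-set normalized enrichment score is computed.
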