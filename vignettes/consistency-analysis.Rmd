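---
title: "Expression consistency analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression consistency analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctcons)
```

## The problem

Single-cell RNA-seq of a nominally homogeneous cell population shows two
kinds of genes: those detected in every cell's library and those detected
only in some. `sctcons` formalises that dichotomy for a small panel of
deeply sequenced libraries (typically four), quantifies how the two groups
differ in expression level and variability relative to a housekeeping-gene
reference, and asks which functional categories each group is enriched for.

The pipeline starts from a gene-by-library FPKM matrix. Everything upstream
— read filtering, alignment, transcript assembly, FPKM estimation — is out
of scope; the matrix is taken as given, with explicit zeros for undetected
genes.

## Expression calls and the CE/IE partition

A gene is called *expressed* in a library when its FPKM strictly exceeds a
threshold, default 0. The strictness matters at the boundary: a value equal
to the threshold is not expressed. We default to bare detection
(FPKM > 0) because assembled FPKM tables of this kind already encode the
upstream pipeline's detection filter in their zeros; whether a biological
floor above detection is appropriate is data-dependent, so the threshold is
exposed rather than hard-coded. Raising it is monotone by construction:
genes can only move CE → IE → unexpressed, never the other way.

Genes expressed in all libraries are CE, in at least one but not all are
IE, in none are unexpressed; the labels are disjoint and cover all genes.
Consistency is undefined for a single library and the partition refuses to
compute it.

The housekeeping panel is evaluated separately: per-library detection
counts, the named unexpressed panel genes per library, genes silenced in
every library, and the CE/IE sub-partition of the panel. Panel genes absent
from the matrix altogether are counted as unexpressed everywhere — a gene
the assembler never reported is, for this analysis, a gene that was not
detected. This makes a transcriptionally silenced control (such as a
promoter-hypermethylated housekeeping gene) behave identically whether it
appears as an all-zero row or is missing.

Gene identifiers are matched case-sensitively and exactly. Duplicate gene
rows are an error by default (`duplicate_policy = "max"` keeps the row with
the largest mean FPKM); duplicates indicate upstream annotation collisions
and silently folding them hides errors.

## Descriptive statistics

**Coefficient of variation.** CV = sample standard deviation (n − 1
denominator) over mean, per gene across libraries. With n = 4 libraries the
denominator convention is material; we use the unbiased-variance
convention. CV is undefined when the mean is 0; such genes are excluded and
counted. For the per-group CV contrast (`group_cv_summary()`) the default
is to compute each gene's CV over its *detected* libraries only
(`zeros = "exclude"`): an IE gene detected in 2 of 4 libraries has a
dropout-driven CV of about 1.15 regardless of how quietly it is expressed
when detected, so including structural zeros would answer "how often does
it drop out" rather than "how much does its expression fluctuate".
`zeros = "include"` is available, and the housekeeping CV table (where
near-universal detection makes the distinction minor) uses it.

**Percentile profiles.** Per-gene means are sorted ascending and sampled at
levels 5%, 15%, …, 95% by nearest rank, `max(1, ⌊level·n + 0.5⌋)` — i.e.
half-up rounding, chosen so that 10 genes at levels 5%…95% return exactly
ranks 1…10. No interpolation: the profile consists of actually observed
values, then log₁₀-transformed. Profiles are non-decreasing in level by
construction and this is asserted on every run.

**Group means.** Per-gene mean FPKM averages over *all* libraries, dropout
zeros included; the group mean averages those per-gene means over the
expressed housekeeping panel, the CE group, the IE group, and all
expressed genes. Including zeros in IE per-gene means is an analysis
choice: it makes the IE group mean reflect the group's effective
transcriptional output across cells, and it is the convention under which
the three group means are comparable on one scale. CE and IE groups
include their housekeeping members — the panel is a reference overlay, not
a third disjoint stratum.

**Correlations and overlaps.** Library-pair Pearson correlations are
computed over genes expressed in at least one of the two libraries, on
log₁₀(FPKM + 1) by default since FPKM spans about five orders of magnitude
(`transform = "raw"` is retained). Overlap analysis works on gene-symbol
sets and reports, per unordered pair, the common count and *both*
directional percentages, plus the full Venn decomposition over all sets;
the Venn region counts must sum to the union size, which the tests verify
against brute-force enumeration.

## Over-representation

For a query of n genes from a background of N, a term/pathway with m
annotated genes and k query hits, the p-value is the exact hypergeometric
upper tail. Two conventions are implemented: `"ge"` (P[X ≥ k], the default
and the conventional over-representation p-value) and `"gt"` (P[X > k],
the summation starting at k + 1). Both are exposed because the second
appears in print in this analysis tradition, but starting the sum above
the observed count makes a fully covered category (k = m) receive p = 0;
we therefore default to `"ge"` and record the convention in every output's
provenance sidecar.

Tail terms are accumulated in log space via `lchoose` with a log-sum-exp
reduction and the result clamped into [0, 1]; a single numeric path covers
all N (the pmf sums to 1 within 10⁻¹² on every fixture tested up to
N = 60, and the tails match exhaustive enumeration of all C(N, n) draws
for every N ≤ 12).

The GO background N is the set of genes annotated in the namespace's
annotation file — not the genome — matching how annotation-file-based
testing is normally done; query genes outside the background are dropped
and reported. Annotations are propagated up the is\_a DAG before testing
(configurable, default on): a gene annotated to a term is implicitly
annotated to every ancestor, with set semantics so diamond motifs count
ancestors once. Obsolete terms carry no propagation edges. Non-is\_a
relationships (e.g. part\_of) are ignored by default since propagation
semantics differ per relationship; they can be requested at parse time.

Ranking is ascending by p-value with deterministic tie-breaking (larger k
first, then term id), so identical inputs give byte-identical output
tables across platforms. Terms with k = 0 are omitted (p = 1 trivially).
No multiple-testing correction is applied to the ranking itself — the
procedure ranks raw p-values — but a Benjamini–Hochberg column is emitted
as a clearly marked extension.

Pathway results additionally carry the coverage rate percent = 100·k/m and
a significance flag: percent > percent\_min AND p < p\_max, both strict
(defaults 80 and 10⁻³; exactly 80% coverage does not qualify).

## The synthetic generator

`synthetic_spec()` describes three gene strata over n\_libraries = 4
libraries:

| parameter | default | meaning |
|---|---|---|
| n\_hkg / n\_ce / n\_ie | 143 / 2000 / 2000 | stratum sizes |
| n\_silenced\_hkg | 1 | all-zero housekeeping controls |
| mu (log₁₀ FPKM) | 3.2 / 1.9 / 0.0 | stratum locations, ~1,600 / ~80 / ~1 FPKM |
| base\_sd (log₁₀) | 0.15 / 0.20 / 0.20 | between-gene spread of base expression |
| noise\_cv | 0.4 / 0.9 / 0.5 | CV of multiplicative library noise |
| p\_detect | 0.5 | per-library detection probability, IE stratum |

Per-gene base expression is log-normal around the stratum location;
library values multiply the base by mean-one log-normal noise
(σ² = log(1 + CV²)). IE genes get independent Bernoulli(p\_detect)
detection masks, redrawn by rejection until neither all-true nor all-false
— rejection rather than truncation preserves exchangeability across
libraries — so the generated labels satisfy the partition definitions
exactly at threshold 0. One global seed drives everything; the ontology
generator uses seed + 1 so regenerating one component never perturbs the
other. The noise CVs are ordered CE > IE ≈ HKG, reproducing the observed
pattern that consistent genes fluctuate more (among detected measurements)
than inconsistent ones, with the housekeeping panel most stable.

`target_means()` gives the analytic expected group means implied by these
parameters: 10^μ·exp((σ₁₀·ln 10)²/2), times, for IE, the expected detected
fraction of the conditioned mask (0.5 at p\_detect = 0.5 with four
libraries). Parameter-recovery tests compare empirical stratum means to
these analytic targets (within 10%, and within 3 standard errors at
smaller sizes). Note the IE target (~0.56 FPKM) is about half the nominal
10^0 scale of its location parameter precisely because per-gene means
average over dropout zeros; the location default was fixed on the FPKM
scale of detected measurements.

The companion ontology is deliberately small (≤ 100 terms, three
namespaces, one diamond motif each, one obsolete term): one
cellular-component leaf is preferentially annotated to CE-like genes
(probability 0.9 vs 0.1 outside) and one to IE genes, and one pathway is
built from 18 CE + 2 IE members so the CE query covers 90% of it. The
pathway collection includes nine random pathways of 30–60 genes so the
planted pathway's members are a minor share of the background — planted
significance is only detectable when the query is not itself the dominant
share of the pathway universe. A null-calibration helper
(`null_enrichment_pvalues()`) draws a term's membership by equal-probability
coin flips, making the query overlap exactly hypergeometric under the
null; at the default granularity (N = 2000, n = 500, m ≈ 400) the p-values
are near-uniform and the false-positive rate at 0.05 sits slightly below
0.05, as expected for a discrete, conservative test.

What the generator does *not* emulate: library-size differences (FPKM is
treated as already normalised), gene–gene correlation, count-level
sampling noise (zeros arise only from the IE masks and the silenced
controls, not from low-count Poisson dropout), transcript isoforms, or any
mapping/assembly artifacts. Passing tests on synthetic data therefore
demonstrate that the estimators and tests are computed correctly and are
well calibrated under the assumed model — not that the model captures
every feature of real single-cell libraries.

## Degenerate inputs and numerical conventions

- Fewer than 2 libraries: partition and downstream analyses refuse.
- All-zero genes: retained with label `unexpressed`, excluded from CV and
  group statistics; a query disjoint from the enrichment background is an
  error listing the unmatched genes.
- Empty groups are omitted from summaries with a warning; fold ratios with
  a zero denominator are `NA`.
- Expression tables are written with `%.17g` so write → read is the exact
  identity; all TSV output is full precision, with rounding (one decimal
  for FPKM means) applied only in the human-readable report.
- Library order is canonicalised by input column order; permuting genes or
  libraries changes no statistic (tested).

## Problem sizes in the test suite

The suite runs entirely offline on generated data: brute-force
hypergeometric enumeration up to N = 12, pmf normalisation up to N = 60,
parameter recovery at the default 2,000 genes per stratum, planted-signal
recovery at 400–600 genes per stratum, and null calibration over 400
replicates — a few seconds end to end. The published four-library MCF-7
summary numbers are checked only when the study's supplementary FPKM table
is supplied by the user (see the README); the table is not redistributed
with the package.

## Known limitations

- The CE/IE partition is threshold-based and binary; borderline genes
  (detected barely above threshold in all libraries) are CE regardless of
  effect size.
- With four libraries, per-gene CVs are noisy (two detected values give a
  CV from two points); group-level summaries are the intended unit of
  interpretation.
- The enrichment background is annotation-file-based; genes never
  annotated are invisible to the test, which is a property of the method,
  not a bug.
- Gene-symbol keying of annotations requires the caller to resolve
  GeneID → symbol for raw NCBI files (`symbol_map` argument); symbol
  collisions across species or history are not arbitrated.
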