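---
title: "Canonical variates analysis of hotspot mutation profiles for malignancy risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical variates analysis of hotspot mutation profiles for malignancy risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Fine-needle aspiration cytology of thyroid nodules returns an indeterminate
(Bethesda III-V) result in a substantial fraction of cases, and molecular
adjuncts are used to tip the rule-in/rule-out decision. A targeted hotspot
panel sequenced on paired tumor and tumor-free thyroid tissue yields, per
sample, a short list of observed variants. `mutcva` turns such variant call
tables into a malignancy risk analysis: variant QC, matched-pair germline
subtraction, mutation matrices, a two-group canonical variates analysis
(CVA), an F-sum risk score, and resubstitution diagnostic metrics. A
synthetic cohort generator calibrated to the published summary statistics of
a papillary thyroid carcinoma (PTC) cohort (39 tumor, 28 tumor-free, 27
matched pairs) makes every stage testable without access to patient data.

## Data model and preprocessing

A variant is identified by the pair (gene symbol, HGVS coding-DNA token),
e.g. `BRAF:c.1799T>A` -- the identity convention of hotspot-panel reports.
Genomic coordinates are optional pass-through. Retention rules, applied
before any statistics, with defaults in `filter_config()`:

* `min_depth = 5` reads covering the call;
* `require_both_strands = TRUE`: support on forward and reverse strands;
* `max_pop_af = 0.01`: population allele frequency at most 1%. "More than
  1%" is read strictly, so a call at exactly 0.01 is retained.

After QC, matched-pair germline subtraction removes any variant key present
in **both** members of a tumor/tumor-free pair from both members. The
removal is per pair, never cohort-wide: the same variant observed
somatically in another patient is information, not germline contamination.
The pipeline order is fixed as QC first, then pair subtraction, and both
steps log their removals into a provenance trail. The two steps commute
when QC evidence is identical within a shared call, but not in general (a
germline variant failing depth QC in the normal only would survive
subtraction); fixing the order makes results auditable.

Two matrices are built from the surviving calls. The variant matrix is
binary incidence (1 = the sample carries the variant), rows sorted by
(gene, token), columns in sample-sheet order -- the canonical sample order
everywhere downstream. The prevalence reduction keeps variants occurring at
least `min_count = 3` times **pooled over both groups**; pooling matters
because benign-tissue indicators reach 3 occurrences only when tumor-free
samples count. The gene matrix counts distinct variant keys per gene and
sample; call multiplicity never inflates either matrix.

## The discriminant model

With two groups the CVA yields a single canonical variate. Writing $W$ for
the pooled within-group covariance of the $p$ variables and
$\bar{x}_T, \bar{x}_N$ for the group mean vectors, the canonical axis is

$$ w \propto (W + \lambda I)^{-1} (\bar{x}_T - \bar{x}_N), $$

and each sample's score is $w^\top x$ mapped by a fixed affine convention:
tumor group high, pooled within-group variance of scores equal to 1, overall
mean 0. Sparse binary data make $W$ singular routinely (any variant absent
from one group), hence the ridge term, $\lambda = 10^{-6}\,\mathrm{tr}(W)/p$
by default and always reported in the fit. At this magnitude the axis is
numerically indistinguishable from the unregularized discriminant whenever
$W$ is well conditioned (the test suite checks correlation above 0.9999
against an independent linear-discriminant fit on random nondegenerate
matrices).

Because the absolute placement of a discriminant axis is arbitrary, only
affine-invariant quantities are comparable across implementations: the
per-variable one-way ANOVA F-ratio

$$ F_j = \frac{\sum_g n_g (\bar{x}_{gj} - \bar{x}_j)^2}{\mathrm{SSW}_j/(n-2)}, $$

the structure correlations $r_j = \mathrm{cor}(x_j, \text{scores})$, and the
classifications. The published variant-level cutoff values (0.136, and
0.322 for genes) are positions on *that study's* axis under *its* software's
convention; they are data-dependent outputs here, never constants. The
correlation screen threshold and the score cutoff coincide numerically in
the published analysis; the package treats them as two distinct quantities
that need not coincide.

Degenerate cases are defined, not special-cased downstream: a variable
constant overall has $F = 0$ and $r = 0$ by convention; a perfect separator
(within-group sum of squares 0, between > 0) carries an infinite-F flag. If
the *scores themselves* collapse within groups (e.g. a single perfectly
separating variable), the unit-within-variance convention is impossible and
the scores are scaled by their total standard deviation instead.

## Indicators, risk score, classification

Variables with $|r_j|$ above a threshold are the indicators: $r_j > 0$
marks tumor (RISK), $r_j < 0$ marks tumor-free tissue (PROTECTIVE). The
threshold is a required, matrix-specific configuration value (the published
analysis derived 0.136 for variants and 0.322 for genes from its own data).

The F-sum risk score of a profile is
$\sum_{j \in \text{selected}} s_j F_j \min(x_j, 1)$ with $s_j = +1$ for RISK
and $-1$ for PROTECTIVE. The sign convention is a deliberate reading: an
unsigned sum would score a carrier of benign markers as high risk,
contradicting the interpretation of negative correlations; `sign_mode`
exposes `positive_only` and `unsigned` alternatives. Infinite F enters the
sum at a configurable cap (default $10^4$) so perfect separators dominate
but remain summable.

Classification uses the canonical axis, not the F-sum: the cutoff is the
score of the all-zero profile, and a sample scoring at or below it -- i.e.
carrying no net mutation signal -- is called tumor-free, anything above it
malignant. The boundary is assigned to tumor-free deliberately: a
mutation-free sample sits exactly at the cutoff and must not be called
malignant. All metrics (sensitivity, specificity, PPV, NPV with tumor as
condition-positive) are resubstitution estimates on the training cohort, as
in the study; no held-out validation or significance machinery is attached,
because the sample size and the exploratory character of the model do not
support it.

## The synthetic cohort generator

`study_template()` encodes the study conditions: 39 PTC / 28 tumor-free
samples from 40 patients with 27 matched pairs and the published histology
distribution; anchor variants at their reported counts -- the BRAF V600E
token in 13/39 tumors and no normals, TSHR c.1373T>C and APC c.636_637insAA
in 4/39 each, the benign LPAR4 c.137A>G in 4/28 normals; the further eight
reported variant-level indicators at 3/39 (3/28 for the benign IDH1 token);
and a background of singletons and doubletons across the remaining genes,
tuned once so the analytic expected tumor mutation count is
$100/39 = 2.56$ and the tumor-free density about a third of that. The
published source reports the APC insertion token inconsistently (insAA in
the text, insA in a figure); the template uses `c.636_637insAA` throughout.
Background tokens are synthetic stand-ins: the study's full per-variant
table is not public, so only the printed aggregate statistics constrain
them.

Sampling is independent Bernoulli per variant and sample at the group
prevalence. That is a deliberate simplification: real co-mutation structure
(BRAF/RAS mutual exclusivity, PI3K-pathway exclusivity) is not emulated by
default -- an optional `exclusivity_groups` field forbids co-occurrence
within listed gene sets for tests that want it -- and per-tumor count
dispersion (the study's range 0-13 includes a 13-mutation outlier no
independent-Bernoulli model reproduces) is only approximated by an optional
lognormal per-sample rate multiplier (`rate_sigma`, default 0). Passing
tests on these cohorts therefore demonstrates correctness of the pipeline's
arithmetic and the recoverability of strong group-skewed signals; it does
not certify performance on real tissue, where linkage between variants,
allele-fraction effects and histology-dependent spectra all exist.

The default QC model is clean (Poisson depth around the study's mean
coverage of 642, both strands, no common-population calls), emulating the
post-QC state of the published dataset; tests that exercise the retention
rules set the QC noise knobs (`p_single_strand`, `p_common_popaf`)
explicitly. One germline AXIN1 variant (the one the study observed shared
between tumor and normal tissue) is injected into both members of a pair
with probability 0.15 to keep pair subtraction exercised end to end.

A note on a property this generator does *not* have: with anchors at their
published prevalences, binomial fluctuation means the BRAF anchor's
realized F-ratio (13.58 at exactly 13/39 vs 0/28) tops the ranking in the
large majority of replicate cohorts but not essentially always -- the benign
LPAR4 anchor realized at 8/28, for instance, has F = 15.1 by the same
ANOVA arithmetic. The acceptance output reports the measured recovery rate,
and the analysis scripts show one replicate where the benign anchor wins.
This is a property of the study conditions themselves, not an
implementation artifact, and the package reports whatever ranking the data
produce.

## Numerical and design choices

* Ridge $\lambda = 10^{-6}\,\mathrm{tr}(W)/p$; reported in every fit;
  overridable.
* Infinite F: flagged, capped at $10^4$ only where it enters additive
  scores.
* Missing population frequency is treated as 0 (rare) and logged: hotspot
  somatic variants are typically absent from population databases.
* The gene-count matrix is analyzed unstandardized by default
  (`standardize = "unit_variance"` is available): the counts share a scale
  and standardization would inflate rare genes.
* Row order lexicographic, column order sheet order, JSON keys fixed:
  repeated runs are byte-identical.
* Pair-shared variant exclusion is per pair; a cohort-wide
  (`global`) interpretation was considered and rejected because it would
  delete somatic events observed in unrelated patients.
* Test and acceptance problem sizes: oracle equivalence on 1000 random
  vectors and 100 random matrices; generator recovery at 200 replicate
  cohorts; end-to-end properties at 100 seeds; chosen as the smallest sizes
  at which the binomial/oracle tolerances are meaningful.

## Limitations

Training-set metrics only, by design. No multi-group extension, no
cross-validation, no probability calibration of the F-sum score (the study
itself attaches no probability level). The VCF dialect reads single-sample
VCFs with configurable INFO keys; multi-sample VCFs and caller-specific
strand encodings beyond per-strand support counts are out of scope. The
generator's independence assumptions are stated above; conclusions about
real-data performance require real data.
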