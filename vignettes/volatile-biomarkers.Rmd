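---
title: "Mining volatile biomarkers for citrus species identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining volatile biomarkers for citrus species identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citrusvol)
```

## The problem

Citrus germplasm collections mix loose-skin mandarins (LSM), sweet
oranges (SW), pomelos (P), lemons (Lem) and hybrids such as clementine
mandarins (CCL) whose fruit can be hard to tell apart morphologically.
Their peel volatile profiles — GC-MS contents of terpenoids, aldehydes,
alcohols and esters in ng/g fresh weight — are species-specific, so a
handful of volatile compounds can serve as chemical barcodes.
`citrusvol` implements the full mining-and-verification workflow: filter
the compound panel by detection support, confirm species structure by
PCA, rank compounds per species by PLS-DA variable importance, gate by a
two-group significance test, and evaluate single-compound
classification rules on an independent verification panel.

## Data model

A volatile profile table is a tibble with `germplasm`, `species` and
`origin` columns followed by one numeric compound column per volatile.
A content of 0 means *not detected*: contents below the instrument's
effective detection limit are recorded as exact zeros, with no separate
missing code and no imputation anywhere in the pipeline. Zeros enter
the significance tests and PLS-DA as numeric 0.

Two preprocessing conventions matter downstream:

* **Presence filter.** A compound must be detected (content > 0) in at
  least `min_germplasms` germplasms (default 5) to be analysed. The
  filter is idempotent and never touches rows.
* **Scaling.** PCA and PLS-DA default to autoscaling (column mean 0,
  variance 1). Pareto and center-only scaling are available.
  Zero-variance columns are centered, assigned scale 1 and flagged, not
  dropped, so compound indices stay stable. Autoscaling is the
  conventional default of the chemometrics software used for this kind
  of screening; contents spanning orders of magnitude would otherwise
  let a few abundant terpenes dominate every component.

## The chemometrics core

### PCA

`fit_pca()` decomposes the scaled matrix by SVD. Loadings are
orthonormal; the explained-variance ratio of a component is its squared
singular value over the total, computed over *all* singular values, so
reported ratios are non-increasing and sum to at most 1 no matter how
many components are requested. Requests beyond the numerical rank are
truncated with a warning. Component signs are fixed by making each
loading's largest-magnitude entry positive.

### NIPALS PLS-DA

`fit_plsda()` dummy-codes group membership as one centered indicator
column per group and runs NIPALS PLS2: for each component the inner
loop alternates weight, score and response-weight updates until the
weight vector moves by less than `tol` (default 1e-10, capped at
`max_iter = 500` iterations with a recorded warning on
non-convergence), then deflates X and the response residual. The first
weight vector is therefore the dominant left singular vector of the
scaled cross-covariance X'Y, which the test suite checks against a
direct SVD. Scores of different components are mutually orthogonal and
every weight vector has unit norm. Two components are the default —
the screening convention matching two-dimensional score plots; a
different `n_components` can be passed throughout.

### VIP

For p compounds, unit-norm weights w_a and per-component explained
response sum-of-squares SSY_a,

VIP_j = sqrt( p · Σ_a SSY_a · w_aj² / Σ_a SSY_a ).

This is Wold's formulation; it forces Σ_j VIP_j² = p exactly, so VIP is
scale-free and VIP > 1 marks an above-average contributor. The
selection gate used throughout is the conventional **VIP > 1.5**.

## Marker mining

`standard_contrasts()` builds the screening design: each of LSM, SW, P
and Lem against the other three of those species (clementines are
excluded from "rest", so a 29/24/8/5 panel yields 29-vs-37 for the LSM
contrast), clementines against their parents LSM + SW pooled, and wild
against cultivar where origin flags exist. Contrasts that cannot
muster two germplasms per side are omitted with a warning.

`select_markers()` combines two gates per compound:

* **VIP > 1.5** from the one-vs-rest PLS-DA fit, and
* **p < 0.05** from `group_difference_test()`, which checks each
  group's normality by Shapiro–Wilk at α = 0.05 (groups smaller than 3
  or with zero variance count as non-normal) and then applies Welch's
  t-test when both groups pass, otherwise the Wilcoxon rank-sum test.
  For two groups a one-way ANOVA is equivalent to the t-test, so the
  normality-gated two-branch design reproduces the usual
  normality-checked ANOVA-with-nonparametric-fallback screening.

Directions come from group medians (means on ties). No
multiple-testing correction is applied by default — the gate is the
plain per-compound p < 0.05 customary in this screening literature —
but `adjust = "BH"` switches the p-values to Benjamini–Hochberg before
gating. Markers are returned sorted by VIP, descending.

## The four-rule classifier

`default_rules()` encodes the published identification protocol as four
*independent* binary classifiers, not a fused multi-class decision:

| marker | species | rule |
|---|---|---|
| β-elemene | LSM | content **strictly greater than 16 ng/g** |
| valencene | SW | detected (content > 0) |
| nootkatone | P | detected |
| limettin | Lem | detected |

The 16 ng/g threshold is taken as a fixed constant of the published
rule; a content of exactly 16 ng/g is classified negative. Accuracies
are kept as exact fractions and only rounded for display
(`format_accuracy()` prints 27/30 as "90.0%"). `load_table2()` ships
the 30-germplasm verification panel (10 LSM, 9 SW, 6 P, 5
lemon-labelled accessions — the lemon group follows the source labels
and includes finger citron and two limes); evaluating the default rules
on it reproduces the published 90.0% / 96.7% / 96.7% / 100.00%
accuracies and the per-rule misclassification lists exactly:

```{r table2}
evaluate_rules(load_table2())
```

## The simulator

The raw 66-germplasm compound table behind the original screening is
not published, so validation uses `simulate_volatiles()`, which emulates
its shape rather than its values:

* **Log-normal abundances.** Background log contents are
  N(`base_log_mean` = log 50, `base_log_sd` = 1) in every species —
  nonnegative, right-skewed, spanning orders of magnitude like real
  peel volatiles. Non-marker compounds are exchangeable across species
  (checked by Kolmogorov–Smirnov in the tests).
* **Planted markers.** Each species receives
  `n_markers_per_species` = 3 compounds (disjoint across species)
  whose log mean is shifted by ±`log_effect` (default 3, i.e. three
  background SDs) inside that species only.
* **Censoring.** Values below `detection_limit` = 1 ng/g become 0, and
  each value is independently dropped with `dropout_rate` = 0.05 —
  hard thresholding plus random dropout, the zero-inflation the
  presence filter must absorb.
* **Geometry.** Defaults are 29/24/8/5/16 germplasms for
  LSM/SW/P/Lem/CCL with a 0.2 wild fraction, mirroring the unbalanced
  panel the contrasts were designed for;
  `recovery_experiment()` defaults to the pure four-species 29/24/8/5
  design so every planted marker has a plain one-vs-rest contrast.

Everything is reproducible from one integer seed; replicate r of a
recovery experiment uses seed + r.

What the simulator does **not** emulate: retention behaviour, spectral
identity, compound-class correlation structure (real terpenoids
co-vary), or biologically structured effect sizes. Passing recovery
tests therefore show that the selection machinery finds shifts of the
planted kind in data of the planted shape — not that 90% of real
biomarkers would be found in a new citrus panel.

## Numerical choices and edge cases

* NIPALS `tol` = 1e-10, `max_iter` = 500; non-convergence warns and is
  flagged on the model rather than erroring.
* Sign conventions (largest-magnitude entry positive) make weights,
  loadings and scores deterministic across platforms.
* Zero-variance compounds inside a contrast get scale 1, weight ~0 and
  a degenerate test result (p = 1, direction "none" when both groups
  are identical constants).
* A response residual that is numerically exhausted stops component
  extraction early, returning fewer components with a warning.
* Tied medians fall back to means for direction; fully tied groups are
  reported directionless.

One behaviour worth knowing when interpreting VIP on raw contents: with
strongly right-skewed (log-normal) abundances, a single extreme value
inflates a column's variance enough to cap its autoscaled correlation
with the class dummy, so even a hugely shifted marker can occasionally
fall below VIP 1.5 in a small panel. At the default study geometry this
affects roughly 1% of planted markers (mean recovery ≈ 0.99 over 50
replicates, computed by the acceptance script); log-transforming
upstream of the pipeline is a reasonable remedy on real data, but is
deliberately not applied by default because the published screening
operated on raw contents.

## Problem sizes used in validation

The packaged validation runs at the study geometry: 66 germplasms
(29/24/8/5), 89 compounds, 3 planted markers per species, 50 simulated
replicates for recovery, 1000 permuted-label replicates at n = 20 + 20
for the type-I error of the significance gate, and 20 randomized fits
for each algebraic identity (VIP normalization, NIPALS/SVD
equivalence). Property tests in the unit suite use smaller matrices
chosen to keep each oracle exhaustive (e.g. exact rank-sum enumeration
at up to 6 + 6 observations).

## Limitations

* Marker VIP/p rankings from the original screening cannot be
  reproduced numerically without its unpublished compound matrix; the
  package validates the algebra and the recovery behaviour instead.
* The 16 ng/g β-elemene threshold is not re-estimated from data;
  learning thresholds is out of scope.
* The four rules are independent binary calls; combining them into one
  multi-class decision (with tie-breaking for germplasms matching zero
  or several rules) is deliberately not provided.
* No OPLS-DA, kernel PLS, or cross-validated Q² diagnostics; an
  optional leave-one-out error could be layered on `fit_plsda()` but
  component choice here follows the fixed two-component screening
  convention.
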