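---
title: "Methods: deriving and validating a prognostic signature for localized PDAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and validating a prognostic signature for localized PDAC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacsig)
```

## The scientific problem

Most patients with pancreatic ductal adenocarcinoma (PDAC) present with
unresectable disease, and even among patients who undergo resection the
majority relapse. Pathological staging (T/N stage, grade, margin status)
separates outcomes poorly. The idea behind this pipeline is that primary
tumors from patients at opposite ends of the clinical spectrum — localized,
resected disease versus metastatic disease — differ in expression in ways
that are prognostic for patients with *localized* tumors: a new resected
patient whose tumor "looks metastatic" molecularly is expected to do worse.

`pdacsig` implements that derivation-and-validation procedure as a
reusable, fully testable pipeline:

1. **Preprocessing** of two-color reference-design arrays: lowess (MA)
   normalization, intensity-based gene filtering, KNN imputation.
2. **Batch adjustment** between the two derivation cohorts with distance
   weighted discrimination (DWD).
3. **Signature selection** by two-class significance analysis of
   microarrays (SAM) at a target false discovery rate of 5%.
4. **Single-sample prediction (SSP)**: nearest-centroid classification by
   `(1 - Pearson correlation)` distance to the resected-class centroid.
5. **Risk stratification** by a survival-optimal cut-point on that
   distance, learned on a training cohort and *frozen* before the test
   cohort is scored.
6. **Validation statistics**: Kaplan–Meier curves, log-rank tests, Cox
   proportional hazards, and contingency-table association tests against
   clinicopathological variables.

## Preprocessing

Expression values are `log2(R/G)` ratios of a Cy5-labeled sample against a
Cy3-labeled common reference. `lowess_normalize()` removes
intensity-dependent dye bias by fitting a lowess curve to M on
A = ½·log2(R·G) and returning residuals; the fit is global (not print-tip
stratified), with span 0.3 — the minimal reading of "lowess normalization"
for this array generation, and the span is exposed for users who want a
stiffer or looser fit.

`filter_genes()` keeps a gene only when at least one channel's mean
intensity *strictly* exceeds 10 in at least 70% of experiments
(`ceiling(0.7 * n)` experiments; a boundary intensity of exactly 10
fails). Spots flagged poor-quality count as failing their experiment; what
constitutes "poor quality" is taken as given via a flag column, since
scanner-specific criteria are not part of this pipeline. The 70% rule is
applied to the pooled experiment set, not per cohort.

`knn_impute()` replaces missing values by the inverse-distance-weighted
mean of the k = 10 nearest gene rows (root-mean-square Euclidean distance
over shared observed columns, so rows with different missingness patterns
are comparable). Exact-match neighbours short-circuit to a plain average,
and distance ties break by row order, making the result deterministic.

## DWD batch adjustment

The two derivation cohorts were collected and processed differently, so
they carry a systematic location bias. DWD finds a separating direction
`w` (‖w‖ = 1) and intercept `b` minimizing

&nbsp;&nbsp;&nbsp;&nbsp;Σᵢ 1/rᵢ + C·Σᵢ ξᵢ, rᵢ = yᵢ(w·xᵢ + b) + ξᵢ > 0, ξᵢ ≥ 0,

with yᵢ = ±1 the batch label. Unlike the SVM, every sample's (inverse)
margin enters the objective, which makes the direction stable when the
number of genes far exceeds the number of samples. Eliminating ξ gives the
equivalent smooth convex loss V(u) = 1/u for u ≥ 1/√C and
V(u) = 2√C − C·u otherwise; `fit_dwd()` minimizes Σ V over the unit ball
by monotone projected gradient descent with backtracking, solving in the
span of the samples (dimension ≤ n) and mapping back to gene space. The
penalty defaults to `100 / median(between-batch pairwise distance)²`, the
standard data-driven heuristic. Convergence is declared at a relative
objective change below 1e−7; non-convergence is an error carrying the
objective trace, never a silent result.

`dwd_adjust()` then translates every batch along `w` so each batch's mean
projection is zero. Both batches move (a symmetric choice — neither batch
is privileged as "reference"; any common target projection differs only by
a global translation that correlation-based classification ignores).
Because the adjustment is a pure translation, within-batch distances and
covariances are preserved exactly. `pca_project()` provides the PC1×PC2
before/after diagnostic.

When tissue annotation is available, the pipeline fits the DWD on the
matched tumor–normal samples of both cohorts, so the adjustment is
anchored on shared biology rather than the tumor-class difference the
signature is meant to capture. How exactly the original procedure used the
pairs is under-specified; fitting on the paired subsets (all tumor and
normal samples of both cohorts) is this package's documented
interpretation. Training and test cohorts are adjusted by fitting a DWD
between the already-adjusted derivation data and the new cohort — the
same mechanism, reused — rather than jointly re-adjusting everything,
which would let test data influence the derivation space.

## SAM signature selection

For gene i, the SAM statistic is

&nbsp;&nbsp;&nbsp;&nbsp;dᵢ = (x̄ᵢ,₂ − x̄ᵢ,₁) / (sᵢ + s₀),

with sᵢ the pooled standard-error scatter and s₀ the exchangeability
("fudge") factor chosen by `compute_s0()` as the scatter percentile
minimizing the coefficient of variation of the windowed median absolute
deviation of d — preventing low-variance genes from dominating. When all
scatters are equal every candidate gives the same coefficient of
variation; the 5th percentile is returned by convention.

Significance is calibrated by label permutations (all distinct
assignments when fewer than `n_perm`, otherwise `n_perm` seeded random
shuffles; with 15 vs 15 samples plain shuffles suffice and balancing is
not enforced). Ordered observed d are compared with the mean ordered
permuted d; for a threshold delta the cut values are the first ordered d
deviating by at least delta on each side, and every gene beyond a cut is
called. The FDR at delta is π₀ times the *average* number of permuted
exceedances divided by the observed call count, with π₀ estimated from
the fraction of observed d inside the central half of the permuted
distribution. The delta actually used is the smallest one whose FDR is at
or below the target (5% by default); if no delta qualifies, nothing is
called — a fallback to "the largest scanned delta" would always call the
single most extreme gene, which is exactly the false call the FDR control
is meant to prevent.

Two documented choices:

* **Mean, not median, false-call summary.** The median permuted
  exceedance count is exactly zero whenever more than half the
  permutations produce no exceedance, which at call counts of one or two
  genes makes the estimated FDR collapse to 0 and calls a gene in roughly
  half of null datasets. The average (the convention of the original SAM
  publication) does not collapse; null simulations then call zero genes in
  the large majority of replicates. `fdr_method = "median"` remains
  available.
* **Two-sided selection.** Signature genes may move in either direction;
  selection is symmetric in d, and the direction of each selected gene is
  visible in its sign.

## SSP classification and risk stratification

`build_centroid()` averages the derivation samples of a class over the
signature genes. Only the *resected* (nonmetastatic-class) centroid is
used for risk calling; the metastatic centroid is computed for
diagnostics. Derivation normals do not contribute to the centroid —
tumors only.

A new sample is scored one at a time: r = Pearson correlation of its
signature-gene profile with the centroid, distance = 1 − r. With a
six-gene signature the correlation is computed over six points and is
accordingly noisy; this is inherent to the design and documented rather
than smoothed away. Distance below the cut-point is low risk; at or above
it, high risk (ties conservatively to poor prognosis). The distance
cut-point of 1 corresponds to r = 0.

`xtile_cutpoint()` learns the cut-point on a training cohort by the
maximally selected log-rank statistic: every midpoint between consecutive
distinct scores leaving at least `min_group = 5` samples per side is a
candidate (the minimum avoids degenerate extreme splits), the two-group
log-rank statistic is computed for each, and the maximizer wins. The
naive p at the optimum ignores the scan and is anti-conservative, so the
Miller–Siegmund minimum-p corrected p is reported alongside it; the
original study instead validated its cut-point on an independent test
set, which the pipeline also does — both safeguards are visible.
`run_pipeline()` freezes the training cut-point before the test cohort is
touched and never re-optimizes it.

## Survival and association statistics

Kaplan–Meier estimation, the log-rank test and Cox regression are
delegated to the `survival` package. The KM median is the first time
S(t) ≤ 0.5 (not the interpolated quantile convention). Cox models use
Efron tie handling by default — overall-survival times recorded in months
guarantee heavy ties, where Efron is more accurate — with
`ties = "breslow"` available for parity with SPSS-style output, which
defaults to Breslow. Rows with missing covariates are dropped and
counted, mirroring "complete data" multivariable analyses. Monotone
likelihood (perfect separation) raises an error rather than reporting a
quasi-infinite hazard ratio.

Association tests between risk groups and clinical variables use the
two-sided Fisher exact test (probability-mass rule) for 2×2 tables and
the uncorrected Pearson chi-square for larger tables; both conventions
reproduce the published contingency-table p-values to the printed third
decimal. Missing clinical values are dropped per variable with counts
logged. The immunohistochemistry score is intensity (0–4) × proportion of
positive cells, with staining in ≤5% of cells treated as negative;
dichotomization at a cutoff (default: sample median) labels scores
strictly above it high, with the boundary value assigned low.

## The synthetic-data generator

`simulate_derivation_sets()` emulates the derivation design: two cohorts
of 15 tumors plus 15 matched normals over the same genes, additive
Gaussian noise on log2 ratios (the standard model in log-ratio space), a
per-gene batch offset of fixed magnitude and random sign added to every
cohort-B sample (the location bias DWD models), and six differential
genes shifted by `effect_size` in cohort-B tumors only. Defaults:
`noise_sd = 0.5`, `effect_size = 1.5` (three noise SDs — strong, clean
class separation of the kind the published six-gene outcome implies),
`batch_shift = 1`. The within-class variance and batch magnitude of the
real arrays are not reported anywhere, so these are free parameters of
the simulation, not estimates of the real data.

`simulate_validation_cohort()` draws half the samples around a supplied
centroid and half around its reflection about the centroid mean, then
assigns each sample's *true* risk label from the sign of its realized
correlation (so labels are consistent with the classifier's geometry even
for borderline draws), and draws overall survival from an exponential
model: baseline hazard `log(2)/20` per month (20-month median, typical of
resected PDAC), hazard ratio 4 for high-risk samples (the magnitude
validated signatures of this kind report), independent exponential
censoring calibrated so each record is censored with probability
`censor_rate` (default 30%). Exponential censoring is the simplest
mechanism satisfying the independent-censoring assumption of the KM
estimator.

What the generator does *not* emulate: gene–gene correlation, array-level
artifacts beyond a location shift, non-proportional hazards, informative
censoring, and real pancreatic gene identities. Passing tests therefore
demonstrate that the machinery is correct under its stated assumptions,
not that the six published genes would re-emerge from the deposited raw
data — reproducing those requires the original arrays, which the pipeline
accepts as input but does not ship.

## Numerical choices and problem sizes

* DWD solver tolerance 1e−7 (relative objective change), iteration cap
  20,000; the monotone line search guarantees a nonincreasing objective.
* SAM permutation count defaults to 1,000; the packaged calibration
  experiments use 100 permutations and 25–50 replicates of 1,000 genes at
  15 vs 15 — sizes at which the permutation FDR is already stable for a
  6-gene effect at three noise SDs.
* Cut-point recovery is evaluated on scores over a discrete grid of eight
  levels (X-tile scans binned marker values). With fully continuous
  scores the argmax of the log-rank process wanders one or two rank
  positions around the true threshold — the drift-to-noise ratio per rank
  step depends only on the log hazard ratio and the event fraction, not
  on n — so exact-gap recovery is an unrealistic yardstick there; the
  binned design matches the procedure's actual granularity.
* Cox recovery uses n = 500 with a binary covariate, where the Wald
  interval at true HR 4 comfortably covers the published-magnitude band.
* Fisher exact p-values are validated against brute-force hypergeometric
  enumeration over all margin-compatible tables.

## Known limitations

* The DWD anchoring on tumor–normal pairs and the independent (rather
  than joint) adjustment of validation cohorts are documented
  interpretations of an under-specified original procedure; both choices
  are isolated behind `run_pipeline()` and can be recomposed from the
  exported functions.
* Six-point correlations are noisy; samples near r = 0 classify
  unstably. The tie rule (high risk) is conservative.
* The maximally selected cut-point is anti-conservative by construction;
  use the corrected p, or better, an independent test set.
* `filter_genes()` collapses duplicate probes by first occurrence and
  does not model background subtraction or dye-swap averaging.
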