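# pdacsig

Derivation and validation of prognostic gene-expression signatures for
localized pancreatic ductal adenocarcinoma (PDAC).

Resected PDAC has dismal and highly variable outcomes that pathological
staging predicts poorly. `pdacsig` implements, as a tested and reusable R
pipeline, a derivation strategy that contrasts primary tumors from the two
ends of the clinical spectrum — patients with localized, resected disease
versus patients with metastatic disease — and turns the resulting gene
signature into a single-sample prognostic classifier for newly resected
patients.

## What the pipeline computes

Given two derivation cohorts (with matched tumor–normal samples), a
training cohort and an independent test cohort:

1. **Preprocess** two-color arrays: lowess (MA) normalization of
   `M = log2(R/G)` on `A = ½·log2(R·G)`; keep genes whose channel mean
   intensity exceeds 10 in ≥ 70% of experiments; impute missing values by
   k-nearest-neighbour gene rows (k = 10, inverse-distance weights).
2. **Adjust batch bias** with distance weighted discrimination (DWD): find
   the direction `w` (‖w‖ = 1) minimizing `Σ 1/rᵢ + C·Σ ξᵢ` over margins
   `rᵢ = yᵢ(w·xᵢ + b) + ξᵢ > 0`, then translate each batch along `w` so its
   mean projection is zero — a pure translation that leaves within-batch
   structure untouched.
3. **Select the signature** by two-class SAM:
   `dᵢ = (x̄ᵢ₂ − x̄ᵢ₁)/(sᵢ + s₀)` with a permutation-calibrated false
   discovery rate; the selection threshold is the smallest delta whose
   estimated FDR is ≤ 5%.
4. **Classify single samples** by the nearest-centroid predictor:
   `distance = 1 − r`, where `r` is the Pearson correlation of the
   sample's signature profile with the resected-class centroid.
5. **Stratify by survival**: learn the optimal distance cut-point on the
   training cohort by the maximally selected log-rank statistic (with a
   Miller–Siegmund corrected p alongside the naive one), freeze it, and
   apply it unchanged to the test cohort.
6. **Validate**: Kaplan–Meier curves per risk group, log-rank test, Cox
   proportional-hazards models (Efron ties; Breslow by flag), and
   Fisher/chi-square association tests against clinicopathological
   variables.

A synthetic-data module (`sim_config()`, `simulate_derivation_sets()`,
`simulate_validation_cohort()`) generates two-cohort studies with a known
batch offset, known differential genes, and survival whose hazard depends
on the true risk label — so every stage of the pipeline is testable with
no external data.

## Worked example

```r
library(pdacsig)

# two derivation cohorts: 15 nonmetastatic (A) vs 15 metastatic (B) tumors,
# each with 15 matched normals, a batch offset, and 6 differential genes
cfg <- sim_config(n_genes = 500, n_per_class = 15, n_de_genes = 6, seed = 42)
der <- simulate_derivation_sets(cfg)
ann <- der$annotation
cohort <- function(b) list(
  expression = der$expression[, ann$sample_id[ann$batch == b]],
  annotation = ann[ann$batch == b, ])

# training (n = 34) and independent test (n = 68) cohorts drawn around the
# true-signature centroid (unknown to the pipeline)
cen_true <- build_centroid(
  der$expression, ann$sample_id[ann$tissue == "tumor" & ann$batch == "A"],
  der$truth$de_gene_ids)
tr <- simulate_validation_cohort(
  sim_config(n_genes = 500, n_per_class = 17, n_de_genes = 6, seed = 43), cen_true)
te <- simulate_validation_cohort(
  sim_config(n_genes = 500, n_per_class = 34, n_de_genes = 6, seed = 44), cen_true)

report <- run_pipeline(
  cohort("A"), cohort("B"),
  training = list(expression = tr$expression, survival = tr$survival),
  test     = list(expression = te$expression, survival = te$survival),
  config   = pipeline_config(sam_n_perm = 200, seed = 7))
report
```

```
Signature pipeline report (complete)
  signature: 6 genes: g0130, g0142, g0202, g0440, g0462, g0478
  training cut-point: distance 0.054 (naive p 1.679e-05)
  test risk groups: high = 38, low = 30
  test log-rank p = 0.0007594
```

SAM recovered exactly the six genes the generator spiked
(`setequal(report$signature, der$truth$de_gene_ids)` is `TRUE`). The
frozen training cut-point stratifies the independent test cohort into
groups with clearly separated survival:

```r
sapply(report$test$km, function(k) k$median)   # median OS, months
#>      high       low
#>  5.466484 14.379266
report$test$cox
#> Cox PH fit (efron ties): n = 68, events = 57 (0 dropped for missingness)
#>                  beta     hr ci_lower ci_upper      p
#> signature_high 0.9312 2.5377   1.4519   4.4354 0.0011
```

High-risk patients die at roughly 2.5 times the rate of low-risk patients
(true simulated hazard ratio 4, attenuated by the handful of borderline
misclassified samples), and the log-rank p below 0.001 confirms the
stratification on a cohort the cut-point never saw.

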