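# radpseudo

Radiomic texture signatures for predicting **pseudoprogression** in
glioblastoma from pre-radiotherapy contrast-enhanced T1 MRI.

Pseudoprogression is a transient post-radiotherapy imaging change that mimics
true tumor progression but resolves on its own or with steroids. Because
managing the two differs fundamentally — observation versus a change of
therapy — a marker that flags, *before* radiotherapy begins, which patients
are prone to pseudoprogression would be clinically valuable. `radpseudo`
implements the full analysis pipeline for building and evaluating such a
marker from tumor regions of interest on pre-treatment MRI, for imaging
scientists and biostatisticians working with small single-institution
cohorts.

## What the package computes

**Feature extraction.** For each patient (a NIfTI volume plus a binary tumor
mask), an IBSI-style catalog of **841 features**: 13 3D shape descriptors,
18 first-order intensity statistics, and 74 texture features from five
matrix families —

* GLCM (co-occurrence): counts of gray-level pairs *P(i, j)* at distance 1
  along the 13 unique 3D directions;
* GLRLM (run length): counts of runs of level *i* and length *j*;
* GLSZM (size zone): counts of 26-connected zones of level *i* and size *j*,
  including `SizeZoneNonUniformityNormalized` = Σⱼ(Σᵢ P(i,j))² / N²_z;
* GLDM (dependence) and NGTDM (neighborhood gray-tone difference) —

computed on the original image (105 features) and on each of 8 sub-bands of
a single-level stationary 3D wavelet transform (L/H filter along each axis;
8 × 92 = 736 features). Preprocessing: resampling to an isotropic 3 mm grid
and fixed-bin-width discretization (`level = floor((x − min)/25) + 1`).

**Feature selection.** A four-stage cascade: per-feature one-way ANOVA
F-tests → Benjamini–Hochberg FDR filter at 0.1 → average-linkage correlation
clustering (distance 1 − |r|, cut at 0.1) keeping each cluster's lowest-FDR
member → sequential floating forward selection (SFFS) maximizing mean
cross-validated AUC of a random forest, returning up to 3 top-ranked
features (hence 7 candidate models: 3 singles, 3 pairs, 1 triple).

**Model evaluation.** Radiomic, clinical (age, gender, location, resection
extent) and combined signatures evaluated by repeated stratified 3-fold
cross-validation (1000 repeats → 3000 held-out fold records) with a
500-tree random forest; Mann–Whitney AUC, average-precision PRAUC, F1, TPR,
TNR, vertically averaged ROC/PR curves, one-tailed paired t-tests between
models, and the operating logit cutoff achieving a target sensitivity on
pooled out-of-fold predictions.

**Synthetic cohort.** Since the motivating clinical dataset is not public,
`generate_cohort()` builds a fully synthetic 35-patient cohort (8:27
pseudoprogression split, demographic marginals of the study population) with
two *plantable* class effects — an intensity-floor shift and a texture
correlation-length change — so the entire pipeline is testable against known
ground truth. See the methods vignette
(`vignettes/radiomics-pipeline.Rmd`) for every convention and design choice.

## Worked example

```r
library(radpseudo)

## a synthetic cohort: 35 patients, 8 pseudoprogression, planted effects
co  <- generate_cohort(cohort_spec(seed = 1), tempfile("cohort"))
tab <- extract_cohort(co)          # 35 x 841 feature table (~20 s)

## univariate check of the two planted feature families
auc(tab$label, tab$original_firstorder_Minimum)
#> [1] 0.9444444
auc(tab$label, tab$original_glszm_SizeZoneNonUniformityNormalized)
#> [1] 0.1435185      # below 0.5: positives have *more uniform* zone sizes

## the selection cascade
sel <- select_features(tab, seed = 1, sffs_repeats = 5, num_trees = 100)
sel
#> <selection_report> 841 screened, 234 passed FDR, 96 representatives,
#>   selected: wavelet_LHL_gldm_DependenceVariance,
#>   wavelet_LLL_firstorder_Maximum, original_glcm_Imc1

## evaluate the 2-feature radiomic signature
cv <- evaluate_model(model_spec("radiomic", sel$selected[1:2], seed = 1),
                     tab, repeats = 100)
cv
#> <cv_result> radiomic signature, 100 x 3-fold CV
#>         metric  mean     sd
#> 1          auc 0.998 0.0124
#> 2        prauc 0.997 0.0254
#> 3           f1 0.962 0.1221
#> 4       f1_max 0.995 0.0354
#> 5          tpr 0.962 0.1339
#> 6          tnr 0.991 0.0370
#> 7 prauc_pooled 0.996 0.0100
```

The minimum-intensity feature discriminates because positives are generated
on a shifted intensity scale with a clamped floor; the zone-size features
discriminate because positives get a longer texture correlation length
(larger homogeneous zones). The cascade finds readouts of exactly these two
planted axes, and a two-feature signature separates the classes far better
than the clinical covariates, which carry no signal by construction
(clinical mean AUC ≈ 0.42–0.49 across seeds, chance level at n = 35).

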