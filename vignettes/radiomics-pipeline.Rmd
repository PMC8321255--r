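---
title: "Radiomic signatures for pseudoprogression: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic signatures for pseudoprogression: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pseudoprogression is a transient post-radiotherapy imaging change in
glioblastoma that mimics true tumor progression but resolves spontaneously or
with steroids. Distinguishing the two matters clinically: pseudoprogression
can be observed, true progression demands a change of therapy. `radpseudo`
implements a radiomics pipeline that asks whether quantitative texture
features of the tumor on the *pre-radiotherapy* contrast-enhanced T1 MRI —
before any treatment effect exists — carry a signal predicting later
pseudoprogression.

The pipeline has four parts: (1) an IBSI-style feature extractor producing
841 named features per patient, (2) a four-stage feature-selection cascade,
(3) repeated stratified cross-validated random-forest evaluation of radiomic,
clinical and combined signatures, and (4) a synthetic cohort generator that
makes all of it testable without patient data.

## Feature extraction

### Preprocessing conventions

* **Resampling.** Images are resampled to an isotropic 3 mm grid (trilinear
  for intensities, nearest-neighbor for the mask) before any texture offset
  is defined; the output grid has `ceil(dim * spacing / target)` voxels per
  axis. Resampling an already-isotropic-at-target image is a no-op.
* **Gray-level discretization.** Fixed bin width of 25 intensity units,
  anchored at the ROI minimum: `level = floor((x - min_ROI)/25) + 1`. Anchoring
  at the ROI minimum (not absolute zero) makes the level count independent of
  background intensities. Each wavelet-derived image is re-discretized
  independently with the same bin width, because each sub-band has its own
  intensity scale.
* **Normalization.** Histogram matching (monotone quantile mapping, 256
  quantile knots) to a configurable reference volume is available
  (`normalize = "histogram_match"`); the reference defaults to the first
  cohort image and is reported when used. It is off by default: the
  extraction conventions do not require it, and on the synthetic cohort it
  would deliberately remove the global intensity-scale class effect that the
  generator plants. N4 bias-field correction is considered an external
  prerequisite and is out of scope; the pipeline accepts already-corrected
  volumes.

### The catalog

The catalog is pinned at 841 features: 105 on the original image (13 shape,
18 first-order, 23 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM) and the 92
non-shape features on each of 8 wavelet sub-bands. Class membership is a
versioned manifest (`feature_catalog()`): GLCM is the 24-feature standard
set minus MCC; first-order is the 19-feature standard set minus plain
standard deviation; shape is the 13 classic 3D descriptors without a
voxel-count volume. Names serialize as `{imagetype}_{class}_{name}`, e.g.
`wavelet_LHL_glszm_SizeZoneNonUniformityNormalized`.

### Texture-matrix conventions

* All pairwise scans use the 13 unique direction offsets at Chebyshev
  distance 1 (one per antipodal pair of the 26-neighborhood). GLCM matrices
  are symmetric; GLCM and GLRLM features are computed per direction on the
  normalized matrix and averaged with equal weights (no distance weighting).
  This direction set is closed under axis permutations and flips, which makes
  the direction-averaged features exactly invariant to those symmetries — a
  property the test suite asserts.
* GLSZM zones are 26-connected components of equal gray level; the matrix is
  direction-free.
* GLDM uses `alpha = 0` (exact level match) and `delta = 1`. The matrix is
  indexed by the raw dependence count `d = 0..26`; feature formulas use the
  conventional shifted index `j = d + 1` so small-dependence emphases stay
  finite at `d = 0`.
* NGTDM uses `delta = 1`; voxels with no valid in-ROI neighbor are excluded
  from both `n_i` and `s_i`.
* Degenerate ROIs (single gray level, single voxel) return defined limits
  instead of NaN: GLCM Correlation = 1, Imc1 = Imc2 = 0, NGTDM Coarseness is
  capped at 1e6, Busyness and Strength are 0 when their denominators vanish.
  Every extracted vector is checked to be finite.

### Wavelet bank

A single-level undecimated (stationary) separable 3D transform with the
Coiflet-1 filter pair and periodic boundary handling produces the 8 sub-bands.
Band labels follow the x, y, z filter order (first letter = x-axis filter).
Neither the wavelet family nor the boundary rule is dictated by the feature
catalog itself; Coiflet-1 with periodic wrapping is this package's
compatibility convention, chosen to match the naming lineage of the catalog
(`wavelet_HHL_...`) and pinned so results are reproducible. The analysis
low-pass sums to `sqrt(2)`, so the LLL band of a constant image `c` is
`c * 2^(3/2)` and every band containing an H letter is exactly zero — both
used as oracle tests.

### Shape

Surface and volume come from a triangulated iso-surface: the binary mask is
zero-padded, lightly Gaussian-smoothed (sigma 0.8 voxel) and the 0.5
iso-level is cut by marching tetrahedra with linear edge interpolation.
The smoothing anti-aliases the voxel staircase, whose jagged triangles would
otherwise overestimate a sphere's surface area badly enough to pull
sphericity far below its analytic limit of 1; with it, the digital ball
phantom's sphericity exceeds 0.97 (asserted by the test suite).
Axis lengths are `4 * sqrt(eigenvalue)` of the physical voxel-center
covariance; elongation and flatness are the usual ratios. Shape features are
computed on the original (pre-wavelet) mask only.

## The selection cascade

1. **ANOVA screen.** One-way two-group F-test per feature, computed in
   closed form (vectorized over 841 features) and cross-checked against
   `stats::aov` in the tests. Zero within-group variance with unequal means
   maps to p = 0; features identical everywhere map to p = 1.
2. **FDR filter.** Benjamini–Hochberg step-up adjustment
   (`stats::p.adjust`), retaining features with adjusted p < 0.1.
3. **Correlation pruning.** Average-linkage hierarchical clustering on the
   distance `1 - |Pearson r|`, cut at height `1 - 0.9`; each cluster keeps
   its lowest-FDR member (ties broken by catalog order). Average linkage was
   chosen to mirror the heatmap clustering convention; absolute correlation
   because anti-correlated features are equally collinear for a classifier.
4. **SFFS.** Sequential floating forward selection maximizing mean
   cross-validated AUC of the same random-forest learner used for final
   evaluation, with a conditional exclusion step that floats a feature out
   whenever that improves the best known score at the smaller size. The
   internal scorer is stratified 3-fold CV repeated 20 times (not 1000 — a
   tractability calibration for a scorer that runs hundreds of times inside
   the search); its fold assignments are fixed by the master seed and shared
   by every candidate evaluation, making the search deterministic and the
   comparisons paired. The SFFS pool is capped at the 20 lowest-FDR cluster
   representatives (`max_candidates`); on the default synthetic cohort the
   uncapped pool of ~110 representatives made a single search run minutes
   long without changing which features win.

SFFS's internal folds are seeded independently of the final evaluation folds;
whether the two should share folds is not determined by the method
description, and independent folds avoid leaking the selection's internal
optimism into the evaluation seed path.

## Model evaluation

* **Learner.** `ranger` probability forest: 500 trees, `sqrt(p)` candidate
  features per split, minimum node size 1, one thread, a fixed seed per
  (repeat, fold). The probability output is the fraction of trees voting
  positive.
* **Cross-validation.** Stratified 3-fold, repeated (1000 repeats for
  headline numbers), per-class fold counts differing by at most one — with
  8 positives and 27 negatives this forces positive counts {3,3,2} and
  negative counts {9,9,9}, so every test fold contains at least two
  positives and fold metrics are always defined.
* **Metrics.** AUC is the Mann–Whitney concordance with 0.5 tie credit;
  PRAUC is step-interpolated average precision. Per-fold average precision
  carries a large small-sample bias — at the forced fold sizes of the 8:27
  split its null expectation is about 0.38, far above the 0.229 prevalence —
  so the summary additionally reports `prauc_pooled`, the average precision
  of each repeat's pooled out-of-fold predictions (null expectation about
  0.30), which is the number to compare against prevalence when asking
  whether a signature carries any signal. F1/TPR/TNR are reported at
  probability threshold 0.5 (a reporting convention, exposed as an argument)
  alongside a max-F1-over-thresholds column, since "F1 from the PR curve"
  admits both readings. Average ROC and PR curves use vertical averaging on
  fixed 101-point FPR/recall grids.
* **Comparison.** One-tailed paired t-test on fold-level AUC differences,
  paired by (repeat, fold); results must share the master seed or the
  pairing is refused. Zero-variance differences resolve by sign (p = 0, 1,
  or 0.5).
* **Operating point.** The logit cutoff is found on pooled out-of-fold
  predictions (per-patient mean over repeats): among probability cutoffs
  achieving TPR at or above the target (0.8), the one minimizing FPR is
  reported on the log-odds scale. Pooled out-of-fold predictions were chosen
  over a single refit model because they exist for every patient without
  refitting and reflect held-out behavior.
* **Clinical encoding.** Age numeric; gender, tumor location and resection
  extent one-hot with explicit Unknown levels; no imputation.

## The synthetic cohort generator

The generator emulates the study conditions: 35 patients with an 8:27
pseudoprogression:non-pseudoprogression split, 64^3 volumes at 1 mm,
ellipsoidal tumors (mean semi-axis 14 mm, 20% per-axis jitter), and clinical
covariates drawn from the study population's marginal frequencies (gender
24:11, the published location and resection-extent tables, ages uniform on
8–87). Covariates are sampled independently of the outcome by default —
matching the weak clinical signal — with an optional flag that plants a
resection-extent association.

Two class effects are plantable, chosen so the two kinds of features in the
published signature (an intensity minimum and a zone-size non-uniformity)
have causal synthetic analogues:

* **Floor effect.** Positives sit on a globally shifted intensity scale
  (`effect_floor`, default 3 noise-SD = 90 units), and the tumor interior is
  clamped 2 noise-SD below its class base, pinning the ROI minimum. The
  shift is global (background included) so it survives partial-volume mixing
  at the tumor boundary during 3 mm resampling.
* **Zone effect.** The interior Gaussian random field of positives is
  smoothed with a correlation length `effect_zone` (default 2) times longer,
  producing larger homogeneous zones and lower zone-size non-uniformity.

Both axes carry between-patient variability (`patient_sd = 45` intensity
units; `zone_jitter = log(2)/2` on the log correlation length), placing each
planted effect two between-patient standard deviations apart. Without this
variability a planted feature separates the classes perfectly, the
cross-validated AUC saturates at 1.0 from subset size one, and the SFFS
search degenerates into arbitrary tie-breaking — a regime that exercises
nothing. `effect_floor = 0, effect_zone = 1` defines the null cohort. The
per-patient latent effect values are recorded in the cohort manifest, which
is what `assess_planted_recovery()` uses to decide whether a selected
signature is built on planted signal (every selected feature Spearman-
correlated at least 0.5 with a latent axis, at least one at 0.7).

What the generator does **not** emulate: MR physics, bias fields, multiple
sequences, anatomical context, registration error, or inter-observer
segmentation variability. Intensity scales are arbitrary units; the study
itself does not characterize its cohort's intensity distributions. Passing
tests on this cohort demonstrate that the pipeline machinery recovers known
planted effects at realistic sample sizes — they say nothing about the
clinical effect size in real MRI data.

## Problem sizes used by tests and the acceptance script

The oracle-equivalence checks use 50 random ROIs of up to 6^3 voxels with up
to 4 gray levels against brute-force enumeration. The pipeline checks use one
full 35-patient cohort (841 features extracted per patient), 20 seeded
cascade runs with a reduced internal scorer (5 repeats, 100 trees — the
planted effects are strong enough that the search outcome is insensitive to
scorer precision), 100-repeat evaluation for signature comparisons, one
1000-repeat evaluation for the record-count contract, and 200 simulated null
cohorts for the false-discovery control. These sizes are the package's
reproducibility budget; all headline machinery (1000 repeats, full scorer)
is available through the same functions.

## Known limitations

* Feature selection and model evaluation share the same 35 patients; there
  is no nested cross-validation, so absolute AUCs of selected signatures are
  optimistic. This reproduces the evaluated design faithfully; an unbiased
  estimate would need an outer validation loop or an independent cohort.
* The wavelet family/boundary and the histogram-matching reference are
  compatibility conventions, not facts fixed by the method description; both
  are configurable and logged.
* The anti-aliased mesh slightly erodes the absolute volume of small
  structures; sphericity, the scale-free combination of volume and area,
  is the accurate quantity.
* Single-voxel and single-level ROIs produce defined degenerate feature
  values rather than errors; downstream screening treats such constant
  features as uninformative (p = 1).
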