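---
title: "Multiphase CT radiomics for RCC subtype prediction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase CT radiomics for RCC subtype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what each stage
models, which parameters matter and why they default to what they do, what
the synthetic cohort does and does not emulate, and where the design was
genuinely open.

## The problem

The three common renal cell carcinoma subtypes — clear cell (ccRCC),
papillary (pRCC), and chromophobe (cRCC) — differ in prognosis and
treatment, but occur at very unequal frequencies (roughly 75/15/5 percent).
Contrast-enhanced CT is acquired in four phases (noncontrast NCP,
corticomedullary CMP, nephrographic NP, excretory EP), and the subtypes
differ both in how strongly the lesion enhances per phase and in lesion
texture. The pipeline asks whether a classifier built on 3D radiomic
features, with all four phases pooled (ALL-P), distinguishes the subtypes
better than any single phase or than a conventional clinical-variable
model — under realistic class imbalance rather than an artificially
balanced design.

## The synthetic cohort generator

No patient images are distributed, so `generate_cohort()` produces a
cohort with the statistical structure the analysis depends on. Per
subject: one ellipsoidal lesion geometry shared by all four phases, four
attenuation volumes, two readers' masks, and a clinical record.

What is emulated, and the parameters that control it:

* **Class imbalance.** `counts` defaults to 209/25/29 (ccRCC/pRCC/cRCC),
  the unbalanced frequencies of a consecutive clinical series.
* **Per-phase enhancement.** Lesion voxels are centred on the published
  median attenuation per subtype and phase (`default_phase_means()`, in
  HU): e.g. CMP 105.31/53.61/85.21. The NCP medians are nearly equal
  across subtypes, so the noncontrast phase is (correctly) the least
  informative. A per-subject, per-phase offset (`subject_sd`, default 8 HU)
  models biological and scanner variability; it is the main knob that
  keeps single-phase models imperfect.
* **Texture.** Within-lesion noise is a Gaussian random field, smoothed
  with a subtype-specific kernel (`texture_sigma`, defaults 2.0/1.1/1.5
  voxels) and scaled to `noise_sd` (12 HU). The correlation length is what
  the GLCM/GLRLM/GLSZM/GLDM/NGTDM families respond to, so texture carries
  subtype signal in every phase. A per-subject log-normal jitter on the
  kernel width (`texture_jitter`, default 0.25) creates within-subtype
  texture heterogeneity; without it, texture alone would make every phase
  nearly perfectly discriminative, which contradicts the intended
  "signal split across phases" regime.
* **Segmentation convention.** Exported masks are the true lesion eroded
  by `margin_mm` (default 2 mm, i.e. round(2/spacing) voxels), emulating
  readers who contour inside the tumour margin to avoid fat and normal
  parenchyma. The CMP contours stand in for NCP (noncontrast boundaries
  are not visible), matching how the masks are reused downstream. The
  second reader is simulated by `perturb_mask()`: `rater_magnitude`
  passes of random boundary-voxel additions/removals (default 1), leaving
  the interior untouched.
* **Inclusions and clinical table.** Cystic (hypodense, -45 HU) and
  calcified (hyperdense, +150 HU) inclusions occur with the per-subtype
  frequencies of the published cohort table; categorical clinical fields
  (sex, side, symptoms, growth pattern, T/N/M, TNM stage) are drawn from
  the same table's per-subtype proportions, which plants the known
  associations (sex, cystic change, N stage) and leaves the rest null.
  Lesion attenuations in the clinical record are recomputed from the
  subject's own voxels (mean HU inside the rater-1 mask), not drawn.
* **Scale.** The default grid is 64³ voxels at 1 mm isotropic — a
  desk-scale stand-in for 512×512×5 mm clinical volumes; spacing is a
  configuration knob and all feature definitions are spacing-aware. The
  bundled analysis scripts and the acceptance checks run 82-subject
  cohorts (60/10/12) on 28³ grids with lesion semi-axes of 6–9 voxels:
  large enough for stable texture matrices, small enough that the whole
  workflow runs in minutes.

What is **not** emulated: organ anatomy, scanner noise physics and
reconstruction artefacts, partial-volume effects, multifocal or infiltrative
growth, and any correlation between clinical variables beyond subtype.
Passing tests therefore demonstrate that the pipeline recovers structure of
this planted kind — not that it would reach any particular accuracy on
patient data, and the published patient-cohort AUCs are deliberately not
targets.

The note on the cystic row: the published table prints ccRCC cystic
"+161 (91.6%)" although 161/207 is 78%; the generator exposes the
probability as a parameter (default 161/207) rather than resolving the
inconsistency.

## Feature extraction

`extract_single_phase()` returns exactly 105 features:
18 first-order + 13 shape + 23 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
5 NGTDM; `combine_phases()` concatenates the four phases to 420 features
with phase-prefixed names in canonical order (NCP, CMP, NP, EP).

Numerical conventions, chosen where the source analysis left them
unstated:

* **Discretization** (`discretize()`): fixed bin width of 25 HU anchored
  at the ROI minimum — the extraction platform's customary default. The
  anchor makes all discretized-texture features invariant to adding a
  constant to every voxel (a tested property).
* **Texture neighbourhoods**: GLCM and GLRLM use the 13 unique direction
  pairs of the 26-neighbourhood at distance 1, with symmetric
  accumulation (GLCM) and feature averaging over directions; GLSZM zones,
  GLDM dependences (alpha = 0) and NGTDM neighbourhoods use full
  26-connectivity.
* **Degenerate ROIs** (single gray level, isolated voxels): entropy-like
  features are 0, uniformity 1, GLCM correlation 1, NGTDM contrast 0 —
  limit values, never NaN. NGTDM coarseness of a perfectly flat region is
  capped at 10^6.
* **Shape**: the lesion surface is extracted by marching tetrahedra on
  the binary mask (isovalue 0.5, voxel centres as sample points, Kuhn
  6-tetrahedron cell split, interface at edge midpoints), giving a
  watertight, consistently oriented mesh by construction; Taubin
  smoothing (20 iterations, lambda 0.5 / mu -0.53) then removes the
  voxel staircase, whose zigzag otherwise inflates the area of oblique
  surfaces by up to ~30 percent. Volume is the divergence-theorem
  integral over the oriented mesh; axis lengths are 4·sqrt(eigenvalues)
  of the voxel-coordinate covariance; maximum 2D/3D diameters are
  largest pairwise surface-voxel distances. A known property of any
  midpoint-interpolated surface on a binary mask is the half-voxel
  chamfer at sharp edges: a 10³ digital cube yields sphericity ≈ 0.85
  where the ideal closed form gives 0.806 (reference marching-cubes
  implementations give 0.849 for the same mask); digital spheres give
  0.95+, approaching 1 with radius. Tests pin both behaviours.
* **Coordinates**: array index order (z, y, x); spacing from the volume
  header; masks binarized at 0.5.

## Reproducibility filter

`icc_two_rater()` implements ICC(2,1): two-way random-effects,
absolute-agreement, single-measurement,
(MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E)) with k = 2.
Absolute agreement is the standard choice for test-retest of feature
values (a consistency form is available via `type = "consistency"`).
Features with ICC strictly above 0.80 are retained, per phase — retained
sets are not intersected across phases, since each phase model stands
alone. Zero-variance features have an undefined ICC and are treated as
not reproducible.

## Stability selection

`run_stability_selection()` implements the ensemble bagging scheme: for
each class's one-vs-rest 0/1 indicator, `n_learners` (default 10) base
learners each run `n_repeats` (default 1000; the analysis scripts use 5,
the tests 3–50) independent stratified shuffles, each shuffle a complete
5-fold cross-validation contributing five LASSO fits (train 80%,
validate 20%). Fits with validation R² > 0.8 are retained; a feature's
frequency is its nonzero-coefficient rate among retained fits, and
features with frequency ≥ 0.2 are selected. The multiclass selection is
the union over the three classes.

Open points resolved here, as the package's own choices:

* **Outcome encoding.** R² is not defined for a 3-class label, so the
  LASSO is run per class on the 0/1 indicator; this keeps the R²
  retention rule meaningful and matches the downstream OvR classifier.
* **Frequency normalization** is by retained fits, not all fits: the
  retention rule is a quality gate, and frequencies should describe the
  fits that passed it.
* **Penalty choice.** Per fit, the penalty is picked from a small
  descending grid (10^-0.5 … 10^-3) as the largest value whose validation
  MSE is within 10% of the grid minimum. A strict minimum-MSE rule keeps
  many near-zero noise coefficients alive and makes nonzero frequencies
  undiscriminating; the parsimony rule restores the sparse-fit behaviour
  stability selection assumes. With `lambda_tol = 0` the strict rule is
  available.
* **Standardization** (mean 0, sd 1) is fitted on each training split
  only, avoiding leakage into the validation R².
* **Empty selection** (nothing retained above the R² bar) returns an
  empty set with a warning and an explicit status, not an exception: at
  desk scale some classes legitimately retain nothing, and the pipeline
  should degrade observably rather than abort.

## Subtype models and evaluation

`fit_ovr_logistic()` fits one unpenalized binary logistic regression per
class on standardized features (IRLS tolerance 1e-8); prediction is
arg max of the three linear scores, exact ties resolving toward the more
prevalent class (ccRCC first). Quasi-separation — likely in small pRCC
folds — triggers a small ridge refit (lambda 0.01), recorded in the model
object. `repeated_stratified_cv()` draws one stratified k-fold partition
per repeat (per-fold class proportions within one subject of the global
ones), fits on k−1 folds, scores the held-out fold, and reports per-repeat
metrics plus a pooled confusion matrix. The binary single-subtype tasks
rerun the same machinery on the 1-vs-rest labels and are summarized by the
mean out-of-fold AUC.

The traditional control model screens clinical variables with
Kruskal-Wallis (continuous) or chi-squared (categorical) tests at
p < 0.05 — screening once on the full table, as a clinician would — and
fits the same OvR logistic on the survivors (factors expanded to indicator
columns; variables with empty expected cells are excluded with a warning).

Evaluation: `confusion_matrix3()` fixes rows = predicted and columns =
pathology (this orientation reproduces the published per-class metrics
from the printed matrices, which is how it was verified);
`per_class_metrics()` returns sensitivity, specificity, precision, NPV,
f1 per class and trace/total accuracy, with NA sentinels for zero
denominators. `roc_auc()` is the midrank Mann-Whitney statistic (ties
half-counted). `delong_test()` builds the variance of a paired AUC
difference from per-positive and per-negative placement values; identical
score vectors give a degenerate flag and p exactly 1. Displayed values
round half-up to 2 decimals (`round_half_up()`); raw values stay in the
CSVs. Comparison p-values are reported unadjusted.

## Problem sizes and determinism

Every stochastic stage takes a seed, and `run_pipeline()` derives
per-stage seeds from one global seed; identical configuration implies
byte-identical reports (a tested property). The bundled analysis runs
82-subject cohorts at 28³ with 2 learners × 5 repeats of selection and
100 CV repeats; the smoke tests use 22 subjects at 20³. These sizes were
chosen so the planted structure is comfortably recoverable while the
complete workflow stays interactive; the selection defaults
(10 × 1000) remain available for full-scale runs.

## Known limitations

* The generator's lesions are smooth ellipsoids with stationary texture;
  none of the shape features beyond size carry subtype signal, and
  margin/infiltration phenotypes are absent.
* At desk scale the R² > 0.8 retention rule keeps few fits (sometimes
  none for the rarest class), so selection frequencies are coarse; the
  union over classes still yields a usable feature set, but per-class
  frequencies should not be over-interpreted at n = 82.
* Mesh-based sphericity of small digital shapes carries the chamfer bias
  discussed above; comparisons between lesions of similar size are
  unaffected, absolute values near sharp corners are.
* The DeLong test assumes fixed scores per subject; applying it to mean
  out-of-fold scores (as stage 6 does) ignores fold-resampling
  variability, the same simplification made in the original analysis.
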