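# rccradiomics

Predicting the histological subtype of renal cell carcinoma (RCC) — clear
cell (ccRCC), papillary (pRCC), or chromophobe (cRCC) — from 3D radiomic
features of multiphase contrast-enhanced CT. The package implements the
full analysis as tested R code for imaging researchers who want to study or
reuse the modelling pipeline: because no patient images are publicly
deposited, a seeded synthetic cohort generator reproduces the statistical
structure the analysis depends on (unbalanced 209:25:29 subtype frequencies,
per-phase lesion attenuation profiles, subtype-dependent texture, two
readers' segmentations).

## The method

For each subject and each CT phase (noncontrast NCP, corticomedullary CMP,
nephrographic NP, excretory EP) the segmented tumour is summarized by 105
radiomic features: 18 first-order intensity statistics, 13 mesh- and
moment-based 3D shape descriptors, and 74 texture features from five
gray-level matrices (23 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) over a
fixed-bin-width (25 HU) discretization. The four phase vectors concatenate
to a 420-feature ALL-P representation.

The pipeline then:

1. **Filters for reproducibility** — per-feature inter-rater ICC(2,1)
   (two-way random effects, absolute agreement, single measurement) between
   two readers' segmentations; features with ICC > 0.80 are retained.
2. **Selects features by ensemble bagging** — base learners run repeated
   stratified 5-fold cross-validations of a LASSO regression on the
   one-vs-rest class indicator; fits with validation R² > 0.8 are retained,
   and features whose nonzero-coefficient frequency reaches 0.2 are
   selected:

   freq(f) = #{retained fits with β_f ≠ 0} / #{retained fits}.

3. **Fits one-vs-rest logistic models** per phase (and ALL-P), predicting
   by arg max of the three class scores, evaluated by repeated stratified
   5-fold cross-validation; the three binary tasks (ccRCC/not-ccRCC, …) are
   scored by AUC.
4. **Benchmarks a traditional model** — clinical variables screened by
   Kruskal-Wallis (continuous) or χ² (categorical) at p < 0.05, then the
   same OvR logistic.
5. **Evaluates** — 3×3 confusion matrices (rows = predicted, columns =
   pathology), per-class sensitivity/specificity/precision/NPV/f1, overall
   accuracy, Mann-Whitney AUC, and the DeLong test for correlated AUCs.

## Worked example

```r
library(rccradiomics)

cfg <- cohort_config(counts = c(ccRCC = 12L, pRCC = 5L, cRCC = 5L),
                     grid = c(20L, 20L, 20L), radius_range = c(4.5, 6.5),
                     seed = 1L)
res <- run_pipeline(run_config(
  cohort = cfg,
  selection = selection_config(n_learners = 2L, n_repeats = 3L, seed = 1L),
  cv_repeats = 5L, seed = 42L))

length(extract_single_phase(res$cohort[[1]]$volumes$CMP,
                            res$cohort[[1]]$masks[[1]]))
#> [1] 105
sapply(res$retained, length)       # ICC-retained features per phase model
#>  NCP  CMP   NP   EP ALLP
#>   67   71   73   63  274
round(sapply(res$models, function(m) m$cv$mean_accuracy), 3)
#>   NCP   CMP    NP    EP  ALLP
#> 0.673 0.636 0.673 0.618 0.873
```

The last line is the point of the analysis: the ALL-P model, which pools
all four phases, classifies the three subtypes more accurately than any
single-phase model (here 0.87 versus 0.62–0.67 on a 22-subject smoke
cohort; the chance level from always predicting ccRCC is 0.55).

Reproducing the published per-class metrics from the printed confusion
matrices:

```r
m <- per_class_metrics(reported_confusion_matrices()$ALLP)
round_half_up(m$accuracy)                  #> 0.8
round_half_up(m$per_class$sensitivity)     #> 0.85 0.60 0.66
round_half_up(m$per_class$specificity)     #> 0.83 0.91 0.91
```

## The analysis workflow

`analysis/` holds numbered drivers that run the study end to end on the
desk-scale synthetic cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort + clinical table (NIfTI/CSV)
Rscript analysis/02_extract_features.R   # 105 x 4 + 420 features, both raters
Rscript analysis/03_filter_icc.R         # ICC > 0.80 retention per phase
Rscript analysis/04_select_features.R    # bagged-LASSO stability selection
Rscript analysis/05_fit_models.R         # OvR models, binary tasks, control
Rscript analysis/06_evaluate.R           # metric tables, DeLong comparisons
```

## Scope

The generator emulates first-order attenuation statistics and plants a
texture signal; it is not an anatomical phantom, and published AUCs on the
undisclosed patient cohort are not reproducible from synthetic data. See
the methods vignette (`vignettes/rcc-subtype-pipeline.Rmd`) for the model
assumptions, parameter choices, and limitations.
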