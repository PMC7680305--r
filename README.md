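# lnrad

CT-radiomics pipeline for predicting histologically confirmed lymph-node
metastasis (LNM) from segmented contrast-enhanced CT lymph nodes.

Small pelvic lymph nodes are hard to classify on CT: the classic short-axis
diameter criterion has poor sensitivity, and PET imaging is not always
available. `lnrad` implements, as a tested and reusable R package, the full
radiomic analysis that this problem calls for: from a 3D CT volume with a
binary node segmentation to a calibrated, decision-curve-evaluated
classifier, with every stage exposed as a tidyverse-style function and a
fully synthetic CT phantom cohort standing in for patient imaging.

## What the pipeline computes

For each segmented node, after isotropic 1 mm resampling (cubic B-spline)
and fixed-bin-width discretization (w = 5 HU, bins anchored at absolute
multiples of w), the extractor emits a fixed 156-feature panel:

* **18 first-order** intensity statistics,
* **10 3D shape** features from a marching-tetrahedra surface mesh
  (sphericity = (36 pi V^2)^(1/3) / A, surface-to-volume ratio, principal
  axis lengths, ...),
* **74 gray-level texture** features from the five matrix families — GLCM
  (13 3D directions, symmetrized, feature-level averaging), GLRLM, GLSZM,
  GLDM, NGTDM,
* **54 local-binary-pattern** features: the 18 first-order statistics of
  three 3D-LBP maps (spherical-harmonic level-1 and level-2 energies of the
  binarized icosphere neighborhood, plus the excess-kurtosis map of the raw
  neighbor differences).

Downstream, the pipeline reproduces the published modeling protocol:

1. **Segmentation robustness** — Dice overlap of two delineations and
   ICC(3,1) (two-way mixed, single-measure, consistency) per feature;
   features with ICC < 0.8 are excluded.
2. **Scanner harmonization** — parametric empirical-Bayes location/scale
   batch correction (ComBat) across scanner models, with a separate
   fit/apply split so test data can be adjusted with training parameters.
3. **Modeling** — l1-penalized (LASSO) logistic models for the texture,
   shape, intensity, LBP and combined feature sets, with lambda chosen by
   10-fold patient-grouped cross-validated deviance, against conventional
   baselines (short diameter, volume, expert rating, SUVmax) fit by plain
   logistic regression; the decision cutpoint is a maximally selected
   rank-statistic split on the training scores.
4. **Evaluation** — ROC/AUC with stratified bootstrap percentile CIs,
   paired AUC comparison (placement-based U-statistic test), confusion
   metrics (MCC, balanced accuracy, PPV, NPV), calibration curves, and
   lymph-node-level decision-curve analysis
   (net benefit = TP/n − FP/n · p_t/(1−p_t)).

## Worked example

Reconstruct a published test-set classification row (49 positive / 13
negative nodes, sensitivity 0.98, specificity 0.69) and verify its derived
metrics:

```r
library(lnrad)
reconstruct_confusion(sensitivity = 0.98, specificity = 0.69,
                      n_pos = 49, n_neg = 13)
#>   TP FP FN TN   mcc balanced_accuracy   ppv npv
#> 1 48  4  1  9 0.744             0.836 0.923 0.9
```

The MCC of 0.744, balanced accuracy 0.836, PPV 0.923 and NPV 0.90 are
recomputed purely from the integer 2x2 table.

Run the complete analysis on the default synthetic phantom cohort
(47 training / 33 testing patients, ~70%/79% LNM prevalence, one in-house
and three external scanners):

```r
res <- run_pipeline(pipeline_config(data = phantom_config(seed = 1),
                                    bootstrap_B = 200, seed = 1))
res
#> <pipeline_result>
#>   158 nodes (92 train / 66 test), 156 features, 111 retained
#> # A tibble: 9 x 5
#>   model               auc_train auc_test    mcc balanced_accuracy
#>   <chr>                   <dbl>    <dbl>  <dbl>             <dbl>
#> 1 Radiomics-texture       1        0.989 0.835              0.918
#> 2 Radiomics-shape         0.5      0.5   0                  0.5
#> 3 Radiomics-intensity     0.694    0.656 0.187              0.599
#> 4 Radiomics-LBP           0.825    0.931 0.747              0.812
#> 5 Radiomics-combined      1        0.992 0.918              0.959
#> 6 LN short diameter       0.597    0.649 0.225              0.607
#> 7 LN volume               0.580    0.591 0.0734             0.542
#> 8 Expert rating           0.759    0.633 0.105              0.532
#> 9 SUVmax                  0.928    0.966 0.566              0.83
```

The held-out ranking mirrors the study the phantom emulates: the combined
radiomic model leads, the LBP-only model clearly beats the intensity-only
model and every conventional CT baseline, while SUVmax (a PET covariate,
included as a biased reference) is near-ceiling. At this seed the ICC
filter retains a single shape feature, so the shape model degenerates to a
null model — exactly what aggressive robustness filtering does to the most
segmentation-sensitive feature class.

Fitted models are regular tidyverse citizens:

```r
m <- res$models[["Radiomics-combined"]]
glance(m)
#> # A tibble: 1 x 6
#>   name               type  n_features n_selected  lambda cutpoint
#> 1 Radiomics-combined lasso        111         16 0.00389   0.0293
autoplot(res$details[["Radiomics-combined"]]$test$roc)
autoplot(res$details[["Radiomics-combined"]]$test$decision_curve)
```

A thin command-line wrapper lives in `inst/cli/lnrad.R`
(`simulate`, `extract`, `robustness`, `harmonize`, `run`).

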