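---
title: "Methods: CT radiomics for lymph-node metastasis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT radiomics for lymph-node metastasis prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lnrad` implements a complete CT-radiomics analysis for classifying
segmented lymph nodes as metastatic or benign: preprocessing, a fixed
156-feature panel, segmentation-robustness filtering, scanner
harmonization, penalized logistic modeling, and held-out evaluation with
decision-curve analysis. This vignette is the package's own account of the
science: the models and their assumptions, the tunable parameters, the
synthetic phantom that makes the pipeline testable, the numerical
conventions, and the known limitations.

## The statistical problem

Each observation is one lymph node: a 3D CT intensity volume (Hounsfield
units) with a binary segmentation, a binary histology label, patient and
scanner identifiers, and optional conventional covariates (short-axis
diameter, expert rating, SUVmax). Nodes are split into a training cohort
(one in-house scanner) and a testing cohort (external scanners). The goal
is a probability of metastasis per node, with all data-dependent modeling
choices — retained features, penalty strength, decision cutpoint — frozen
on the training cohort before the test cohort is scored. Multiple nodes
per patient are correlated; cross-validation folds are therefore grouped
by patient so a patient never straddles a fold boundary (plain stratified
folds are available as an option).

## Preprocessing

* **Resampling.** Images are interpolated to an isotropic grid (default
  1 mm) with a cubic B-spline, using the exact recursive prefilter (pole
  $\sqrt3-2$, mirror boundaries, closed-form initialization for short
  axes) so the spline interpolates the input samples; masks are
  interpolated linearly and re-binarized at 0.5. The interpolation order
  and the mask rule are package conventions — common practice, but worth
  stating because neither is universal.
* **Discretization.** In-mask intensities are binned at a fixed width of
  5 HU with bin edges anchored at absolute multiples of the width:
  $\mathrm{bin}(x) = \lfloor x/w\rfloor - \lfloor \min x/w\rfloor + 1$.
  Anchoring at multiples of $w$ (not at the per-node minimum) keeps edges
  scanner-independent and makes shifting all intensities by a whole
  number of bins a no-op for every discretization-based feature — a
  property the test suite asserts. A typical contrast-enhanced node spans
  a few dozen bins.

## The feature panel

The panel is fixed at 156 uniquely named features and ships as a JSON
manifest (`feature_manifest()`): 18 first-order statistics, 10 shape
features, 74 texture-matrix features (23 GLCM, 16 GLRLM, 16 GLSZM, 14
GLDM, 5 NGTDM) and 54 LBP features. The composition is a reconstruction
of the standard panel this size and is labeled as such: 24 standard GLCM
features minus the SumAverage duplicate of JointAverage, and a shape set
without the per-plane 2D diameters and the redundant voxel-volume entry
(`shape_features()` still reports `VoxelVolume`; it is simply not part of
the 156-feature panel).

Conventions that matter for reproducibility:

* **Surface mesh.** Surface area and mesh volume come from a
  marching-tetrahedra triangulation (six tetrahedra per cube, linear edge
  interpolation) of a 2×2×2 mean-filtered copy of the binary mask. The
  anti-aliasing step places the 0.5 iso-surface at the physical voxel
  boundary and removes the staircase bias that makes raw binary meshes
  overestimate area; on digital spheres of radius 3–10 voxels the area
  error is within ~3% and digital-ball sphericity lands in [0.95, 1].
  Masks too thin to survive the filter (under ~2 voxels across,
  including single voxels) fall back to meshing the raw binary field, so
  no mask ever produces a degenerate mesh or a division by zero.
* **Texture aggregation.** GLCM and GLRLM are computed per direction (13
  unique 3D directions at distance 1) and features are averaged across
  directions — feature-level averaging, not matrix merging, matching the
  default of the common extraction tools. Direction-averaged features are
  exactly invariant under 90° grid rotations.
* **Degenerate values.** Features undefined on constant VOIs return a
  documented fallback (correlation-type features 1, everything else 0;
  NGTDM coarseness capped at $10^6$), keeping feature tables rectangular.
* **Oracle testing.** On small VOIs every matrix (GLCM, GLRLM, GLSZM,
  GLDM, NGTDM) is checked element-wise against naive triple-loop
  enumeration, and representative features of every family against naive
  formula recomputation.

## The 3D local binary pattern filter

No standardized 3D LBP definition exists, so the package's construction
is an explicit design choice, surfaced as configuration. For every voxel,
intensities are sampled by trilinear interpolation at 42 points on a
sphere of radius 1 mm (an icosahedron subdivided once), mirror-padded at
volume borders. The binary pattern $s_j = [I(x_j) > I(x_0)]$ is projected
onto the real spherical harmonics of degree 1 and 2, and the per-degree
energies form the level-1 and level-2 maps; harmonic energies are
approximately rotation-invariant (the suite asserts < 5% change under 90°
rotations). The third map is the *excess kurtosis of the raw
neighbor-minus-center differences* — the binarized samples would have
trivial kurtosis — with zero-variance neighborhoods mapped to 0. The
filter is invariant to adding a global constant to the image. The 18
first-order statistics of each map restricted to the mask give 54
features (`lbp-m1_*`, `lbp-m2_*`, `lbp-k_*`).

## Segmentation robustness and harmonization

**ICC(3,1).** Feature stability across two blinded delineations is
quantified by the two-way mixed-effects, single-measure, *consistency*
intraclass correlation — the form the Shrout–Fleiss "(3,1)" numbering
identifies: $(MS_R - MS_E)/(MS_R + MS_E)$ for two raters. Consistency ICC
ignores fixed rater offsets and common affine rescaling; it is computed
on raw feature values. Features with ICC < 0.8 are excluded before
modeling; constant features are excluded with a degenerate flag, and the
filter is idempotent. The paired subset defaults to 20 training patients.

**ComBat.** Scanner effects are removed by parametric empirical-Bayes
location/scale harmonization: per-feature standardization (batch-size
weighted grand mean, pooled residual variance), per-batch location and
scale estimates shrunken by the standard normal / inverse-gamma priors
with moment-matched hyperparameters, solved by fixed-point iteration
(relative tolerance $10^{-6}$, 100 iterations). The fit is label-blind:
no biological covariates enter the design, which is a caveat — strong
class imbalance across scanners would leak into the correction. By
default parameters are fit on training and testing cohorts jointly (the
protocol of the study this reproduces); a train-only mode exists and is
the right choice for genuinely prospective use. The implementation is
cross-checked against `sva::ComBat` in the test suite, and singleton or
unseen batches are explicit errors rather than silent passthroughs.

## Modeling and evaluation

LASSO logistic models (via glmnet's coordinate descent, internal
standardization) are fit per feature class and for the combined set;
$\lambda$ minimizes the 10-fold cross-validated binomial deviance
(`lambda.min`; the 1-SE rule is available). Fold assignment is
seed-deterministic, patient-grouped and class-balanced, with automatic
re-stratification if a fold loses a class. A feature set reduced to a
single retained feature is fit unpenalized (there is nothing to select);
an empty set skips the model with a warning. Conventional covariates are
fit by maximum-likelihood logistic regression with Wald CIs;
(quasi-)separation — which an ordinal expert rating can easily produce —
is detected and reported as an unstable estimate with a (0, Inf) CI
rather than as a spuriously precise one.

The decision cutpoint is the maximally selected rank statistic on the
training scores: among candidate splits (midpoints of consecutive
distinct scores with split proportion in the inner 10–90% range), the one
maximizing the absolute standardized two-sample linear rank statistic.
The suite checks it against exhaustive enumeration and a permutation
null. Degenerate (all-tied) score vectors from null models fall back to a
majority-call cutpoint.

Evaluation: AUC is the Mann–Whitney concordance with midrank tie
handling (ties count ½), invariant under monotone transforms; bootstrap
CIs use class-stratified resampling (the small negative class makes
unstratified resamples lose a class) with percentile intervals; paired
model comparison uses per-observation concordance placements and a
normal test on the placement-covariance-scaled AUC difference; the
decision curve reports net benefit
$NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)$ per lymph node against the
treat-all and treat-none references. `reconstruct_confusion()` inverts
published sensitivity/specificity and class counts into the integer 2×2
table, enabling internal-consistency checks of printed classification
tables to their printed precision.

## The synthetic phantom

No patient imaging ships with the package; the first-class
`generate_cohort()` module produces a fully synthetic two-cohort dataset
with the statistical structure the analysis assumes. What it emulates:

* two cohorts (default 47 training / 33 testing patients, 1–3 nodes
  each, ~70% / 79% node-level prevalence);
* small soft-tissue lesions: log-normal volumes with mean ≈ 0.15 cm³
  clamped to [0.05, 1.05] cm³, ellipsoids with random orientation,
  eccentricity and smooth spherical-harmonic surface modulation,
  voxelized at an anisotropic CT spacing (0.75 × 0.75 × 1.5 mm);
* contrast-enhanced intensities: benign base 45 ± 8 HU between nodes,
  +6 HU for metastatic nodes, voxel noise 3 HU, a darker background
  (−12 HU), and a 0.5 mm Gaussian point-spread blur of the noiseless
  structure (partial-volume effect at the boundary);
* label-dependent *texture structure*: band-limited multiplicative
  fields with correlation length 1.8 mm (benign) vs 3.2 mm (metastatic).
  The metastatic amplitude (0.41 vs 0.36) is chosen so the *realized*
  within-lesion variance matches the benign value — a coarse field hides
  most of its variance in the between-node mean — so the class signal
  lives in spatial structure (visible to texture-matrix and LBP
  features) rather than in first-order statistics, mirroring a study
  regime in which LBP features dominate and intensity models are weak;
* scanner batch effects: additive offsets (−12 to +15 HU) and
  multiplicative gains (0.95–1.10) per scanner, one in-house training
  scanner and three external testing scanners;
* a second independent segmentation for 20 training patients: the mask
  surface is displaced by a smooth random field (correlation length
  4.5 mm) plus a per-mask constant bias (30% of the displacement
  variance, truncated at 1.5 SD — raters differ systematically in
  generosity but do not grossly re-segment a node), with total magnitude
  0.85 mm calibrated so the median Dice across the default lesion mix is
  ≈ 0.89. The systematic component is what makes shape features the
  least segmentation-robust class;
* weak conventional covariates: a mild volume–label coupling (+0.25 on
  the log scale), an expert rating built as a noisy ordinal
  discretization of label and diameter, and a strongly separating
  log-normal SUVmax surrogate.

All intensity levels and effect sizes are free parameters of the phantom
with documented defaults — not literature measurements. Where a target
regime was stated (the Dice band, the prevalence, cohort sizes, the
qualitative model ranking, the shape-vs-LBP robustness ordering), the
defaults were calibrated once against that regime and then frozen.

What the phantom does **not** emulate — and hence what passing tests do
not show about real data: no anatomical context (no neighboring organs,
vessels or fat planes), no contrast-phase or kernel variation beyond
affine scanner effects, no spatially correlated CT noise, no PET volume,
and real inter-rater disagreement is only approximated by a displacement
model. Absolute AUCs on the phantom say nothing about clinical
performance; the pipeline's value claims are the *relative* orderings and
the correctness of each statistical component against independent
oracles.

## Problem sizes and determinism

Everything stochastic takes a seed: the cohort generator reproduces
bit-identical data for a fixed seed (restoring the caller's RNG state),
fold assignment and bootstrap resampling are seed-deterministic, and
rerunning a pipeline configuration reproduces identical metrics. The test
suite runs the texture oracles on ≤ 5³ VOIs, robustness and pipeline
properties on reduced cohorts (14 + 10 patients), support-recovery
simulations at n = 200 with 3 informative + 50 noise features over 10
seeds, and the end-to-end ranking on the full default phantom; these
sizes are the package's chosen trade-off between statistical resolution
and a test suite that stays fast enough to run habitually.

## Known limitations

* The 156-feature manifest is a reconstruction; a different canonical
  list with the same total would change individual feature values but
  not the pipeline's structure.
* The 3D-LBP construction (icosphere sampling, harmonic levels, kurtosis
  map) is one principled reading of an under-specified filter; radius
  and sampling density are configuration, and other constructions would
  yield different feature values.
* ICC filtering with ~40 paired nodes is itself noisy; per-class
  exclusion fractions fluctuate across seeds even though their ordering
  is stable.
* Joint (train+test) ComBat fitting uses test-cohort feature
  distributions during harmonization; use `combat = "train"` for strict
  prospective hygiene.
* Node-level decision curves treat nodes as independent decisions;
  patient-level aggregation is out of scope.
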