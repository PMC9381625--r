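---
title: "Methods: auto-fixed VOI radiomics with prostate masking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auto-fixed VOI radiomics with prostate masking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Manual slice-by-slice segmentation of prostate lesions is the bottleneck of
MRI radiomics: minutes per lesion, with substantial reader influence.
`dlmvoi` implements a semi-automatic alternative that needs one mouse click
per lesion: the click is repositioned onto the lesion's lowest-ADC voxel, a
sphere of fixed diameter is rasterized around that voxel in physical
millimetres, and voxels outside a whole-prostate segmentation are removed.
Radiomics features computed from this masked sphere feed a feature-selection
and gradient-boosting pipeline that classifies lesions as clinically
significant (CS, ISUP grade group ≥ 2 analogue) or not.

The package contains seven cooperating parts: a synthetic bpMRI phantom
generator, the VOI method, the feature extractor, joint-mutual-information
feature selection, the optimized classifier, ROC-based evaluation, and the
file-format/CLI glue.

## The VOI method

**Click repositioning.** Radiologists click the *visually* darkest part of
the lesion on the ADC map; the true minimum voxel may be a neighbour. The
search region is the 56-voxel neighbourhood: all integer offsets
$v \neq 0$ with $\|v\|^2 \le 5$. This is the unique small Euclidean lattice
ball with exactly 56 elements (shells of squared norm 1, 2, 3, 4, 5 hold
6 + 12 + 8 + 6 + 24 offsets); we adopt it as the definition of
"56-connectivity", which is otherwise not a standard connectivity class.
The neighbourhood radius is configurable for sensitivity analysis, and the
search is deliberately a single pass — one neighbourhood check of the
click, not an iterated descent.

**Outlier robustness.** Candidates are scored by the mean ADC over the
candidate and its available face neighbours (up to 7 voxels, restricted to
the grid and the prostate mask). A single noise voxel with an extreme value
cannot dominate a 7-voxel mean, so the seed lands in a genuinely dark
region rather than on a speckle minimum. Ties break by (1) score,
(2) physical distance to the click, (3) lexicographic $(k, j, i)$ order —
fully deterministic.

**Sphere and masking.** A voxel belongs to the sphere iff the physical
distance between voxel centres is $\le d/2$ (non-strict, voxel-centre
convention, 0-based indices). Spacing is anisotropic — by default
$0.5 \times 0.5 \times 3$ mm, so the sphere spans many in-plane voxels but
few slices. The sphere is then intersected with the prostate mask; a
quality check errors if the seed voxel itself would be removed, because the
seed is by construction inside the lesion and hence the prostate — losing
it can only mean the mask is defective. The initial diameter is swept over
6–30 mm in 2-mm steps (13 values) when optimizing the VOI size.

## Feature extraction

Per sequence (T2, ADC, high-b DWI) and per lesion VOI:

* **Normalization**: whole-image z-score (population SD), multiplied by
  100. With unit-variance images a bin width of 30 would collapse the
  histogram to a single bin; scale 100 yields discretized images with tens
  to low hundreds of gray bins, the intended operating range of the
  fixed-bin-width scheme.
* **Discretization**: gray level $= \lfloor (x - \min_{VOI})/W \rfloor + 1$
  with $W = 30$.
* **First order** (18 features): computed on the full 3D VOI voxel set;
  entropy and uniformity use the discretized histogram; percentiles use
  linear interpolation (R type 7); variance and moments are population
  moments; kurtosis is non-excess.
* **Texture** (24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM):
  forced-2D at distance 1, i.e. per axial slice with in-plane 8-neighbour
  connectivity. GLCM and GLRLM build one matrix per (slice, direction) for
  the four in-plane directions; GLSZM, GLDM, NGTDM build one matrix per
  slice. Features are computed per matrix and averaged **uniformly over
  the separate matrices**; slices (or directions) contributing no valid
  matrix are skipped from the average, not zero-filled. GLDM dependence is
  1 + the number of equal-level neighbours ($\alpha = 0$); NGTDM excludes
  voxels with no valid neighbour.

This yields 93 features per sequence, 279 per lesion. No resampling and no
image filters are applied.

Degenerate conventions, fixed once and used by both the implementation and
the test oracle: skewness and kurtosis of a constant input are 0; GLCM
correlation of a zero-variance matrix is 1; MCC of a single-level matrix is
1; NGTDM coarseness is capped at $10^6$ when its denominator vanishes.

Matrices are indexed by the gray levels actually present (empty levels are
dropped per matrix); features that reference the number of gray levels
(IDMN, IDN, NGTDM contrast) use the per-matrix count of occupied levels.

## Feature selection: JMIM

Continuous features are discretized to 10 equal-frequency bins (plug-in MI
practice; the bin count is configurable and ties are kept stable by
quantile cut points). The first selected feature maximizes $I(f; Y)$; each
later pick maximizes $\min_{s \in S} I((f, s); Y)$ — the maximin joint-MI
criterion, not the JMI sum. Ties break by column order. The estimator is
the plug-in contingency-table estimator in bits; no bias correction is
applied because only the argmax matters.

## Model optimization

The cohort is split 4:1 at lesion level, unstratified, by a seeded
permutation (`floor(4N/5)` training rows; 524 lesions give 419/105). An
optional patient-grouped split keeps all lesions of a patient on one side.

Each optimizer trial evaluates a nested objective on training rows only:

1. **Stage 1** — a randomized five-times-repeated 5-fold split; JMIM runs
   on each of the 25 training portions; features are ranked by selection
   frequency (ties by mean selection rank, then column order) and the
   top-$k$ are kept. Aggregating over folds rather than fitting once makes
   the selected list robust to individual lesions.
2. **Stage 2** — stratified 10-fold cross-validation of an extreme
   gradient boosting classifier (`gbtree`, binary logistic) on the top-$k$
   features; the objective is the mean area under the precision–recall
   curve over the validation folds, which remains informative under class
   imbalance.

The search space is $k \in [2, 40]$, boosting rounds $[5, 200]$, depth
$[2, 6]$, learning rate log-uniform $[0.01, 0.3]$, and positive-class
weight in $[r/2, 2r]$ where $r$ is the training negative/positive count
ratio. The sequential optimizer draws 10 random trials, then samples
around the best quartile of completed trials with occasional fresh random
draws; every trial shares the same nested splits (common random numbers),
so trial objectives are directly comparable and the whole run is a
deterministic function of the seed. The best trial's parameters and
stage-1 feature list are refit on all training rows.

Whether the final feature list should come from a single selection fit or
from fold-frequency aggregation is genuinely open; the package aggregates
(the more stable choice) and also exposes `jmim_select()` directly for the
single-fit variant.

## Evaluation

AUC is the normalized Mann–Whitney statistic (ties one half). Confidence
intervals use the DeLong variance with a normal approximation, clipped to
$[0, 1]$. Model comparison is the **paired DeLong test**: a multi-reader
multi-case variance model would be meaningless here because each model
produces exactly one score vector over identical cases, so the standard
paired-AUC test replaces it. The operating threshold maximizes Youden's
$J$ (predict positive at score $\ge t$, scan observed scores, lowest
threshold on ties); among the possible threshold criteria Youden is the
conventional default and the one adopted here. Empirical (unsmoothed)
ROC curves are used for all statistics.

The diameter sweep re-runs extraction, optimization and test evaluation at
each of the 13 diameters on one fixed lesion-level split, so the 13 AUCs
differ only through the VOI size.

## The phantom

The generator emulates the data contract of a multi-center bpMRI cohort:

* gland = axis-aligned ellipsoid, default half-axes 20×17×13 mm jittered
  ±12% per case, on a 96×96×20 grid at 0.5×0.5×3 mm (the anisotropy is
  deliberate: it stresses the physical-mm sphere rasterizer);
* lesions (1–2 per case, radius 4–8 mm) with ADC cores depressed below
  gland tissue — defaults 600 (CS) / 950 (non-CS) / 1400 (gland) in
  ADC-like units, a contrast ordering the package validates; intensity
  blends linearly from core to rim, so VOIs see lesion edges and healthy
  tissue;
* lesion texture = multiplicative smoothed Gaussian random field, rougher
  for CS lesions (amplitude 0.35, correlation 2 mm) than non-CS (0.12,
  5 mm), so texture — not just intensity — carries class signal;
* 9 centers with multiplicative intensity scale U(0.8, 1.25) and additive
  Gaussian noise of SD U(15, 60) ADC units, scaled per sequence in
  proportion to its gland-level intensity;
* 35% of lesions are placed within 5 mm of the gland boundary, so a naive
  18-mm sphere demonstrably leaks outside the prostate and the masking
  step does real work;
* clicks = the true in-lesion ADC minimum jittered by ≤1 voxel
  (Chebyshev), constrained to the mask.

The ADC contrast and texture amplitudes are free parameters with no
canonical reference values; they were fixed once at values a radiologist
would call a clear-but-noisy case mix, strong enough that recovery tests
are well-posed. T2 and DWI level sets are internal
constants with the clinically expected contrast directions (lesions mildly
dark on T2, bright on high-b DWI).

What the phantom does **not** model: MR physics and b-value dependence,
zonal anatomy, registration error between sequences, non-ellipsoidal gland
shape, and realistic lesion morphology. Passing recovery tests therefore
shows the pipeline is correct and sensitive under controlled conditions —
not that any particular clinical AUC would be reached on real data; no
clinical performance claim is made or reproducible here, since cohorts of
this kind are private.

## Problem sizes used by the checks

The test-suite and acceptance script use sizes chosen to keep full runs in
the minutes range while leaving every statistical check well-powered: the
default cohort is 120 cases (≈185 lesions, 40% CS) with a budget-30
optimization for parameter recovery; the diameter sweep uses 60 cases with
budget 10 per diameter; DeLong coverage uses 1000 simulated cohorts of
n = 200 and null-uniformity 2000 replicates of n = 100; the
feature-extractor oracle comparison uses 25 random small VOIs against a
naive loop-based reference implementation at 10⁻⁶ relative tolerance.

## Known limitations

* The per-(slice, direction) matrix averaging is one defensible reading of
  "averages of separate matrices"; pooling counts across slices per
  direction before computing features is another, and the two differ for
  nonlinear features on multi-slice VOIs.
* The feature set is fixed at 93 features per sequence (279 per lesion
  over three sequences). Pipelines that additionally extract features
  from several diffusion b-value images would have larger tables; the
  package treats the sequence list as configuration rather than guessing
  extra inputs.
* The plug-in MI estimator is biased upward for small n; this affects
  selection order only through near-ties.
* The optimizer is a light sequential sampler, not a full tree-structured
  Parzen estimator; with the budgets used here (tens of trials) both
  reduce to seeded argmax over trials, which is the reproducibility
  contract the package guarantees.
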