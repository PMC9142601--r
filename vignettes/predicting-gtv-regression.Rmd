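---
title: "Predicting early tumor regression from planning CT: methods and design"
author: "DLRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting early tumor regression from planning CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DLRadiomics)
```

## The problem

During the first weeks of head-and-neck radiotherapy many gross tumor
volumes (GTVs) shrink quickly. That shrinkage moves target coordinates
and can degrade both target coverage and sparing of organs at risk, which
is why adaptive radiotherapy (ART) re-plans treatment mid-course.
Re-planning is expensive, so a prediction made *before* treatment starts
— will this tumor regress early or not? — lets clinics reserve frequent
adaptation for likely regressors.

`DLRadiomics` implements a transfer-learning radiomics pipeline for that
prediction. The outcome is binary: a patient is a *regressor* when their
volume-loss rate

$$\Delta \mathrm{GTV}/\text{day} \;=\;
  100 \cdot \frac{V_\mathrm{init} - V_\mathrm{boost}}{V_\mathrm{init}}
  \Big/ \text{days}$$

exceeds a threshold, by default the cohort median (`labelByThreshold()`,
strict `>`; a rate exactly at the threshold labels 0, since a median
split leaves the boundary unassigned). The predictors are *deep
features*: activations of a frozen, ImageNet-pretrained CNN applied to a
standardized 2D crop of the tumor, optionally compared against 107
handcrafted radiomics features and a small clinical-factor table.

## Image preprocessing

`preprocessTumor()` turns a planning CT plus GTV mask into a model-ready
crop in six deterministic steps:

1. **Isotropic resampling** to 1 mm (nearest neighbour, both CT and
   mask). The output grid is anchored at the input origin and covers the
   input physical extent; this convention is stated explicitly because
   nearest-neighbour grids differ between toolkits.
2. **Maximum-area axial slice** of the mask (ties: lowest slice index).
3. **100 mm x 100 mm crop** centered on the tumor center of gravity.
   The center of gravity is computed in 2D on the selected slice — the
   crop is 2D and the multiple-tumor rule below operates within the
   slice — and rounded to the nearest pixel (half-way ties toward the
   lower index). If the initial crop contains several 8-connected tumor
   components, the crop is re-centered once on the centroid of the
   largest component inside the crop. Out-of-volume pixels are padded
   with the background fill value.
4. **Background masking**: non-GTV pixels are set to the *global*
   minimum of the resampled volume (per-volume rather than per-crop, so
   the fill is stable across crops of one patient).
5. **Windowing** with level 50 HU / width 350 HU: a linear map of
   [-125, 225] HU onto [0, 1] with clipping. Output is stored in [0, 1];
   any backbone-specific channel normalization belongs to the backbone
   adapter, because pretrained networks disagree about their expected
   input scale.
6. **Bilinear resize** to the backbone input size and replication into
   three identical channels, matching the RGB input convention of
   natural-image networks. The per-backbone input edge length is plain
   configuration (`model_input_px`).

The whole chain is a pure function: identical inputs give a bit-identical
`TumorCrop`.

## Feature extraction

Real backbones (the 16 ImageNet CNN families the approach was designed
around) are *adapters* registered at run time with `registerBackbone()`;
pretrained weights are never bundled. The package ships a deterministic
**stub backbone**: `tanh(Wx + b)` with `W`, `b` drawn once from a seeded
normal stream. It is pure, reproducible across platforms, injective with
high probability, and produces the same 1000-feature-per-crop geometry as
a real backbone, so every downstream stage is testable without network
weights. For architectures without a final fully connected layer the
adapter declares that it taps the layer before the last softmax instead.

Deep features are z-scored per column (`zscoreNormalize()`), with the
sample (n-1) standard deviation — the convention is documented because
either denominator is defensible. Statistics are computed on the full
analysis cohort before any resampling, mirroring the internal-validation
workflow this pipeline targets; that choice carries a known optimistic
bias, and conclusions drawn from it are internal validation, not external
performance. Constant columns map to zeros with a warning rather than
failing, so degenerate features cannot crash a long run.

The 107 handcrafted features (14 shape, 18 first-order, 75 texture:
GLCM 24, GLRLM 16, GLDM 14, GLSZM 16, NGTDM 5) are computed by a
backend behind `registerRadiomicsBackend()`. The built-in `"internal"`
backend implements the standard catalogue directly in R, in 3D on the
1 mm grid with a fixed 25 HU bin width anchored at the ROI minimum.
Direction-dependent matrices (GLCM, GLRLM) use the 13 unique 3D
directions and average feature values over directions; GLSZM zones and
GLDM dependencies use the 26-neighbourhood. Two approximations are
documented: mesh volume is approximated by the voxel volume, and surface
area is estimated by the coarea formula — the integral of the gradient
magnitude of the gently smoothed (sigma 0.8 voxels) mask indicator —
which reproduces the analytic area of a 10 mm digital sphere to within
about 1%, giving sphericity 1.00 +/- 0.05 on spheres.

## Feature selection

Selection is two-step, followed by ranking:

* **Robustness.** Features are recomputed over families of alternative
  segmentations and kept only when their intraclass correlation exceeds
  0.7 (strict). The ICC is the two-way mixed, absolute-agreement,
  single-measurement form, computed from the ANOVA mean squares:
  $$\mathrm{ICC} = \frac{MS_R - MS_E}
    {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$
  The citation trail for "Case 3A" stops short of a formula; the
  McGraw–Wong convention above is the standard reading and is pinned by
  an ANOVA-oracle test. An all-constant matrix has no defined ICC; such
  features are dropped with a warning.
* **Collinearity.** Among retained features, while any pair has Spearman
  `|rho| > 0.8` (absolute value — anti-correlated duplicates are equally
  redundant), the currently strongest pair is examined and the member
  with the higher mean `|rho|` against all other retained features is
  eliminated (ties: higher column index), then correlations are
  re-examined. Each iteration removes one feature, so termination is
  guaranteed, and the post-condition (no retained pair above 0.8) is
  verified by exhaustive scan in the tests. Processing pairs in
  descending `|rho|` order is a choice: the method's literature is
  ambiguous about ordering, and this order is deterministic and removes
  the worst offenders first.
* **Ranking.** Five filter rankers each produce a top-10 list:
  - `CHSQ`: chi-square independence of the class against the feature
    discretized into 10 quantile bins (the bin count is configuration —
    toolboxes that bin continuous predictors rarely say how); score
    `-log10(p)`.
  - `WLCX`: two-sample Wilcoxon rank-sum, score `-log10(p)`.
  - `NCA`: diagonal neighbourhood component analysis — non-negative
    per-feature weights (squared parametrization) maximizing expected
    leave-one-out stochastic-neighbour accuracy with ridge penalty
    `lambda = 1/n`, L-BFGS from an all-ones start, seeded.
  - `ReliefF`: expected margin over k = 10 nearest hits/misses for all
    instances, Manhattan distance, miss terms weighted by class priors.
  - `infFS`: infinite feature selection. Features are graph vertices
    with adjacency
    `a_ij = alpha * max(s_i, s_j) + (1 - alpha) * (1 - |rho_S(i,j)|)`,
    `alpha = 0.5`, and the score sums weighted paths of all lengths:
    `S = (I - rA)^{-1} - I` with `r = 0.9 / spectral_radius(A)`. For the
    relevance term `s_i` this package uses a normalized Fisher-type
    class separation `|mu_1 - mu_0| / s_pool`, scaled to [0, 1]. A raw
    per-feature spread term — the usual unsupervised choice — is
    uninformative here because the features arrive z-scored (every
    spread is 1, and pooled within-class spread would actually *demote*
    informative features), so the supervised separation term is the
    design that makes the ranker do its stated job on normalized input.

  Scores are sorted descending with a documented index tie-break;
  ordering compares scores at 10 significant digits so that numerically
  degenerate ties (identical features passed through eigendecompositions
  or optimizers) remain stable.

Clinical factors skip the ICC and collinearity steps (the factor list is
already small) and are encoded as one ordinal column per factor —
matching how filter rankers consume them and the convention that a
staged factor is one predictor, not a one-hot block. HPV status is a
three-level factor (positive / negative / not applicable).

## Classifiers

Five algorithms sit behind one fit/score contract (`fitClassifier()` /
`predictScores()`): random forest (100 trees, `sqrt(p)` split
candidates), RBF-kernel SVM (`C = 1`, `gamma = 1/(p Var(X))`, decision
values as scores), k-nearest-neighbour voting (`k = 5`, Euclidean,
index-stable tie handling), Gaussian naive Bayes with sklearn-style
variance smoothing, and LDA with automatic Ledoit-Wolf shrinkage of the
pooled covariance. The original study's exact hyperparameters live in an
unavailable supplement, so these defaults are deliberately ordinary,
surfaced in configuration, and individually overridable; results
obtained with them are not claimed to reproduce any cohort-specific
number. The smoothing and shrinkage choices are not cosmetic: small
bootstrap in-bag sets routinely contain features that are constant
within a class, and the plain textbook fits fail or return NaN there,
while the regularized forms degrade gracefully. Globally constant
columns get LDA weight zero, which also makes score ordering invariant
to padding the design with constant features. Scores are class-1
probabilities where the model has them and decision values otherwise;
AUC is rank-based, so the distinction never matters for the estimator.

## Evaluation

The estimator of record is the **0.632+ bootstrap AUC** with B = 1000
replicates:

$$\widehat{AUC}_{0.632+} = \frac{1}{B}\sum_{b=1}^{B}
  \left[(1 - a(b))\,AUC(X, X) + a(b)\,AUC'(X^{*b}, X^{*b}(0))\right]$$

with `AUC'` the out-of-bag AUC clamped below at 0.5,
`a(b) = 0.632 / (1 - 0.368 R(b))`, and the relative overfitting rate
`R(b)` equal to 1 when the out-of-bag AUC is at or below chance,
`(apparent - oob)/(apparent - 0.5)` when `apparent > oob > 0.5`, and 0
otherwise. The apparent AUC does not depend on the replicate and is
computed once per feature subset. Replicates whose in-bag or out-of-bag
set contains a single class are skipped and logged with the effective B
— the estimator's definition is silent on them, and skipping is the only
choice that leaves the remaining replicates' arithmetic untouched.
Sensitivity and specificity at each classifier's default operating point
(0.5 on probabilities, 0 on decision values; the operating point is a
documented choice, not a published one) are blended with the same
`(1 - a(b)) / a(b)` weights.

**Forward selection** greedily grows a subset from a ranker's top 10,
accepting a candidate only on strict improvement of the 0.632+ AUC (ties
stop the search). All candidate subsets share one replicate list —
common random numbers — which removes between-candidate Monte-Carlo
noise and makes the search deterministic given the master seed.

The **model grid** crosses the five rankers with the five classifiers
(25 cells); each cell is a forward-selection result and the summary is
the mean and SD over completed cells.

Competing feature sets are compared with the **corrected resampled
paired t-test**
`t = mean(d) / sqrt((1/K + n_test/n_train) s_d^2)`, df = K - 1,
one-tailed (the alternative is that the first model is better). Because
bootstrap replicates have varying set sizes, the size ratio uses the
mean in-bag-distinct and out-of-bag counts over the replicates — about
61/35 for a 96-patient cohort and 50/29 for 79, which the tests verify
against seeded resampling.

The **threshold sweep** relabels the cohort at a list of rate thresholds
(0.46 — the median — through 3.2 %/day for primary tumors, 1.4 through
4.1 %/day for nodal), balances classes by down-sampling the majority
without replacement 100 times per threshold, and averages the 0.632+ AUC
over under-samplings. Balanced thresholds reduce to a single plain
evaluation; thresholds that empty a class are skipped with a warning.
A Spearman check of each selected feature against initial tumor volume
(`volumeCorrelationCheck()`) flags volume surrogates.

## Synthetic data: what it emulates and what it does not

The generators exist so that every stage is exercisable end-to-end with
known ground truth and no patient data:

* `makePhantom()` builds ellipsoidal tumors (default semi-axes
  20/16/12 mm) of smoothed Gaussian HU texture (mean 60, SD 25 HU,
  1.5 mm correlation length) on a constant -100 HU background — enough
  structure for deep and handcrafted features to be non-trivial, with no
  claim of anatomical realism.
* `perturbSegmentations()` emulates inter-observer contouring: each of
  nine raters' masks is the 0.5 level set of the smoothed indicator
  shifted by a seeded offset plus a smooth noise field, scaled so the
  boundary moves by roughly the requested millimetres. Dice overlap
  decreases monotonically with magnitude; magnitude 0 reproduces the
  input exactly.
* `makeFeatureCohort()` plants the selection module's whole branch
  structure: informative features with a standardized class shift
  `delta`, redundant copies tuned to a target Spearman correlation via
  the Gaussian rank-correlation identity `rho_S = (6/pi) asin(rho_P/2)`
  (noise is scaled by the parent SD so the target holds for shifted
  parents too), and independent noise. Defaults are the study-scale
  conditions: n = 96, balanced median split, 50 candidates, delta = 1
  (a moderate, clinically plausible effect), redundancy 0.9.

Passing tests on these cohorts show that the machinery is correct and
calibrated — a planted delta = 1.5 effect is recovered with the
closed-form binormal AUC `Phi(delta/sqrt(2))` to within 0.05, a null
cohort stays within [0.45, 0.55] — not that any particular clinical AUC
is reproducible. The headline cohort results of the motivating study
depend on private patient CTs and are out of scope by design.

## Numerical and reproducibility choices

* All randomness flows from a master seed through named substreams
  (`deriveSeed()`), with the RNG kind pinned; no stage reads global
  random state, and reruns are byte-identical at fixed thread count.
* Tie-breaks are uniformly "lowest index wins" (max-area slice, centroid
  rounding, ranker ordering, KNN neighbour order) and each is asserted
  in tests.
* Degenerate-input policy: empty masks, single-class labels, all-equal
  rates and empty candidate lists are errors; constant feature columns,
  undefined ICCs and single-class bootstrap replicates degrade with
  warnings/logging instead, because they occur naturally inside long
  resampling loops.
* Desk-scale problem sizes in the test-suite: phantoms of 30–64 voxels
  per edge, cohorts of 40–200 samples, B of 10–200 with B = 1000
  reserved for the bootstrap size checks, U of 5–8 in sweep tests.
  These sizes were chosen so the full property suite gives tight Monte
  Carlo tolerances; the pipeline's reduced-mode flags (`B`, `U`) are
  first-class configuration and reduced runs are labeled as such in the
  provenance block.

## Known limitations

* The stub backbone validates plumbing and statistics, not the
  representational power of any real CNN; absolute AUCs on stub features
  mean nothing clinically.
* The internal radiomics backend follows the standard formula catalogue
  but is not a certified IBSI implementation; mesh-based shape features
  are approximated as described above.
* z-scoring and feature selection on the full cohort are internal
  validation; external generalization requires refitting the whole chain
  inside the resampling loop, which this package does not do (matching
  the workflow it implements).
* 2D crops discard out-of-slice information by construction.
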