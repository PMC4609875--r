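---
title: "Volumetric texture features and gravitational search feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric texture features and gravitational search feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voitex)
```

## Scope

voitex implements a classification pipeline for masked regions of 3D scalar
images (the motivating application is T1-weighted brain MRI with expert-drawn
lesion masks, benign vs malignant): a 77-dimensional volumetric texture
descriptor, wrapper feature selection by a gravitational search metaheuristic
that simultaneously tunes the hyperparameters of an RBF support vector
machine, and a leave-one-out evaluation layer. Because clinical volumes are
rarely shareable, the package ships a phantom generator whose statistical
structure exercises every stage; all quantitative statements below are
reproduced by the test suite on those phantoms, not on patient data.

## Preprocessing

Volumes are normalized with a 3D Laplacian-of-Gaussian filter whose kernel at
displacement $(x,y,z)$ is

$$
C\!\left[\frac{x^2}{\sigma_x^4}-\frac{1}{\sigma_x^2}
      +\frac{y^2}{\sigma_y^4}-\frac{1}{\sigma_y^2}
      +\frac{z^2}{\sigma_z^4}-\frac{1}{\sigma_z^2}\right]
e^{-x^2/2\sigma_x^2-y^2/2\sigma_y^2-z^2/2\sigma_z^2}.
$$

The continuous kernel integrates to zero; truncation to a finite grid breaks
that, so the discrete kernel is mean-subtracted after truncation
(`dc_correct = TRUE`), restoring a zero response to constant volumes.
Defaults are $\sigma = 1$ voxel isotropic, $C = 1$ and a truncation radius of
$4\sigma$ (at least $3\sigma$ is enforced); boundaries are handled by
reflection. Whether downstream features should be computed on filtered or raw
intensities is genuinely open — the normalization is described as
preprocessing, but the feature definitions do not reference it — so the
pipeline exposes `use_log_filter` (default `TRUE`) and `extract_cohort()`
accepts `log_params = NULL` for raw intensities.

In-mask intensities are quantized by min–max linear binning into
$G$ gray levels (default $G = 16$; no canonical value exists). Quantization
is monotone, constant regions map to level 1, and $L$ — the longest
bounding-box edge — bounds the admissible co-occurrence distances at $L/2$.

## The 77-feature descriptor

All statistics are computed over the 13 unique directions of the 26-voxel
neighborhood (one offset per antipodal pair, `direction_table()`).

* **Co-occurrence block (5).** For each direction and each distance in the
  default set $\{1, 2\}$ (configurable up to $L/2$), pairs of quantized
  levels with both voxels in-mask are counted, symmetrized and normalized.
  Entropy (base 2, positive by the standard Haralick convention),
  homogeneity, contrast, energy and correlation are averaged over directions
  and distances. A degenerate marginal yields correlation 0; directions with
  no valid pairs are skipped from the average.
* **Run-length block (11).** Maximal runs of equal level along every lattice
  line parallel to each direction, with out-of-mask voxels breaking runs.
  The eleven classical statistics (SRE, LRE, LGRE, HGRE, SRLGE, SRHGE,
  LRLGE, LRHGE, GLNU, RLNU, RPC) use the standard Galloway definitions; the
  nonuniformity statistics square the marginal run counts.
* **Centroid-line block (61).** The region centroid is the mean in-mask
  coordinate rounded to a voxel (ties toward the lower index). Through it, a
  maximal digital ray is traced along each of the 13 orientations; the
  profile is the ordered sequence of in-mask levels. Twelve distribution
  statistics (mean, population variance, mean absolute deviation, standard
  deviation, skewness, excess kurtosis, median, min, max, range, and
  histogram energy and entropy) are computed on the pooled levels of all 13
  lines (12 features), per line and then aggregated across lines by mean,
  min, max and range (48 features), plus the mean line length (1 feature).
  The total of 61 and the ingredient statistics are fixed by the method; the
  exact pooling/aggregation layout is this package's reconstruction, since
  only the totals and the statistic names are canonical. Zero-variance
  profiles have skewness and kurtosis 0 by convention.

Layout: 61 `sclgm_*`, 5 `glcm_*`, 11 `rlm_*` — 77 named values
(`feature_layout()`), invariant to region translation and deterministic.

## Gravitational search and the refined variant

Candidate solutions are agents in $[0,1]^n$. Per iteration $t$ of $T$:
fitness-derived masses $m_i = (\mathrm{fit}_i - \mathrm{worst}) /
(\mathrm{best} - \mathrm{worst})$, normalized to $M_i = m_i / \sum_j m_j$
(uniform when all fitnesses tie); gravitational coefficient
$G(t) = G_0 e^{-\alpha t/T}$; pairwise forces
$G\,M_i M_j (x_j - x_i) / (R_{ij} + \xi)$ from the $K$ best agents, $K$
shrinking linearly from $N$ to 1; acceleration $F_i / M_i$ (zero for
zero-mass agents); velocity $v' = \mathrm{rand}_i\, v + a$ and positions
clamped to the cube. Positions *and* velocities are initialized uniformly.
Defaults follow the published configuration: $N = 100$, $T = 500$,
$G_0 = 100$; $\alpha = 20$ is the standard decay (no published value), and
$\xi = 10^{-6}$.

Each pairwise force is weighted by a random coefficient indexed by the
attractor: uniform on $[0,1]$ in the classical variant, Bernoulli$(p)$
(force exists or not; default $p = 0.8$, no published value) in the refined
variant. The refined variant additionally replaces the uniform velocity
memory with a two-branch draw: with probability 0.6, $\ln(1/U)/4$ (a
heavy-tailed exploration term with mean $1/4$), otherwise $0.4 + 0.1Z$ for
standard normal $Z$. The printed form of the logarithmic branch is ambiguous
("$\ln(1/\mathrm{rand_d}4)$"); it is parsed as $\ln(1/\mathrm{rand_d})/4$,
and the result is clamped to $[0,1]$ since an unbounded velocity-memory
coefficient would let velocities diverge. Both are interpretation decisions.
Bookkeeping is elitist: the reported optimum is the best position ever
evaluated, and the per-iteration history is monotone.

The iteration cap is the stopping rule (the alternative evaluation-count
phrasing is redundant given a fixed population size).

## Wrapper selection and classification

An agent of dimension $d + 2$ decodes to a feature mask (coordinates
thresholded at 0.5; an empty mask is repaired to the single highest
coordinate) and log-uniform $C \in [0.1, 100]$, $\sigma \in [0.1, 10]$. The
wrapper fitness, maximized (negated for the minimization engine), is

$$\theta \cdot \mathrm{accuracy} + (1-\theta)\cdot\mathrm{featuresel}^{-1},
\qquad \theta = 0.7,$$

with accuracy the stratified 5-fold cross-validated accuracy of the RBF SVM
on the masked features. Stratified 5-fold (rather than leave-one-out) keeps
the search tractable; the fold assignment is drawn once per run so the
fitness landscape is fixed. The published SVM parameter table is internally
inconsistent (a millisecond "simulation time", a fractional feature count),
so hyperparameters always come from the decode or from `tune_svm()`.

The evaluation layer standardizes features by training-fold statistics
(zero-variance columns pass through unscaled — a generic solver's built-in
scaling produces NaN models on constant columns, which are common for
extreme-value features on small cohorts). Leave-one-out evaluation reports
confusion counts (+1 = malignant = positive), sensitivity, specificity,
accuracy, RMSE and MAE on the 0/1 class encoding (predicted classes, not
scores — the definition is ambiguous), and the ROC: a threshold sweep over
signed decision scores, trapezoid area, and the max(TPR − FPR) vertex as the
operating point. Zero-denominator metrics are `NA`, not 0. A
leave-one-out fold whose training set degenerates to one class predicts the
majority. `tune_svm()` grid-searches $C \in 10^{\{-1..2\}}$,
$\sigma \in 10^{\{-1..1\}}$ by stratified CV with ties broken toward the grid
center: at small $n$, CV accuracy has coarse granularity and ties are
frequent, and corner configurations (tiny $C$, huge $\sigma$) that tie on
balanced CV folds collapse to majority-class prediction under leave-one-out's
inherently imbalanced training folds. The baseline classifier is
leave-one-out $k$-nearest-neighbor ($k = 5$, odd so binary votes cannot
tie); paired classifier comparisons use the two-sided Wilcoxon signed-rank
test on per-subject losses (all-zero differences give $p = 1$).

A standalone geometric benchmark fitness (sum of squared distances from a
decoded point to all region voxels, minimized at the centroid, infeasible
points penalized) is exposed for optimizer demonstrations; it plays no role
in feature selection.

## The phantom generator

Each subject is an ellipsoidal lesion (default semi-axes $8\times8\times6$
voxels in a $24\times24\times20$ grid) in independent Gaussian background
noise (mean 50, sd 10). Lesion texture is Gaussian white noise smoothed by
an isotropic Gaussian of the class *correlation length*, standardized, then
scaled to the class mean and noise sd — the smallest model with a tunable
co-occurrence/run-length signature. Defaults chosen once for the study
conditions: both classes mean 100, noise sd 10, correlation length 1 voxel
(label +1, rough) versus 3 voxels (label −1, smooth); no canonical contrast
exists for the clinical classes, so these are free parameters of the
phantom, not estimates of tissue properties. Smoothing raises
neighbor co-occurrence similarity, so the rough class has higher mean GLCM
contrast — the monotone separation the tests check. Sub-seeds derive from
the master seed by counter offset, making cohorts of any size reproducible.
The phantoms deliberately omit MRI physics (bias fields, Rician noise,
partial voluming); passing tests demonstrate the pipeline's statistical
machinery, not clinical performance.

The tabular generator emits class-conditional Gaussians in which only `k` of
`d` columns differ between classes (by `effect` noise standard deviations),
with the informative index set recorded — ground truth for selection
experiments.

## Problem sizes and observed behavior

The suite runs at desk scale: oracle equivalence on 100 random $5^3$ masked
volumes, optimizer checks at $N = 20$ agents and $T \le 100$ iterations,
wrapper runs on $n = 60$, $d = 30$ tables and on 10-subject phantom cohorts.
Two documented behaviors deserve emphasis:

* **The parsimony term caps informative-feature recall.** On tables with
  $k = 5$ informative of $d = 30$ columns at 3-sd separation, CV accuracy
  saturates at 1.0 for any subset containing a couple of informative
  columns; from there the $\mathrm{featuresel}^{-1}$ term makes dropping
  further informative features costless, so the fitness optimum is a
  near-singleton subset. Mean recall of the informative set measures ≈ 0.5
  at the tested budget and would *decrease* with a stronger optimizer. High
  recall and aggressive parsimony are structurally incompatible under this
  fitness.
* **Tiny cohorts defeat wrapper selection.** At $n = 10$, the internal CV
  granularity is 0.1 and the search overfits its fixed folds; under the
  same tuned leave-one-out evaluation, random subsets of equal size match
  or exceed the selected subset on the default phantoms, where most of the
  77 features carry class signal. The corresponding end-to-end comparison
  is kept in the suite as a negative result.

## Limitations

Single binary classification task; no multi-sequence input; no probability
calibration; the centroid-line layout is a reconstruction (see above); the
back-propagation baseline of the original comparison is unspecified and
therefore omitted in favor of the $k$NN baseline.
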