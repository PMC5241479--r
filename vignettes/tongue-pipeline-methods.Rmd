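---
title: "Methods: tongue body/coating segmentation, feature extraction and GA-SVM classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tongue body/coating segmentation, feature extraction and GA-SVM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguedx)
```

This vignette is the package's own account of its methods: the models and
procedures, the tunable parameters and why their defaults are what they
are, the numerical choices, and what the synthetic fixtures can and cannot
establish.

## The problem

Tongue inspection scores two structures on a standardized tongue
photograph: the *body* (the flesh, with red as the dominant hue, ranging
light white to crimson to purple) and the *coating* (the surface fur,
white through yellow to grey). A diagnostic classifier built on tongue
images therefore needs (i) a body/coating segmentation, (ii) numeric color
and texture descriptors per region, and (iii) a classifier trained on those
descriptors together with basic covariates (gender, age, BMI). All stages
here assume a pre-cropped image: the tongue-region mask is an input, not
something the package detects.

## Segmentation

### Chrominance axis

Body and coating differ mainly in chrominance, not luminance. The default
working axis is CIELAB a\* (red–green opponent): body pixels sit high
(red), coating pixels near zero or below (neutral-to-yellow pales have
small a\*). HSI hue and the raw R−G difference are selectable alternatives
(`segmentation_config(chroma_channel = )`). With the default synthetic
colors, body a\* ≈ 23.5 and coating a\* ≈ −1.4 — a gap of ~25 units against
within-region spreads of 2–4 units.

### Division phase

The tongue bounding box is split quadtree-style while a block's within-mask
a\* standard deviation exceeds `homogeneity_tol` (default 6 chrominance
units) and the block holds more than `min_block_size` pixels (default 4,
i.e. blocks bottom out at 2×2). `min_block_size` is interpreted as a pixel
*count* so that splitting continues far enough for boundary blocks to be
small; terminal blocks that remain inhomogeneous — generically the blocks
straddling the body/coating boundary — are dissolved into single-pixel
regions rather than left as mixed blocks. `homogeneity_tol = 6` sits well
above the a\* noise of realistic texture/noise settings (≈1) and well below
the body–coating gap (≈25), so pure blocks stop splitting immediately and
mixed blocks always split.

### Merge phase

Regions are merged greedily in region-index order (indices follow the
column-major position of each region's first pixel; ties go to the lower
index): each region attempts to merge with its adjacent region of closest
mean chrominance, and the merge is accepted when the merged standard
deviation stays within `homogeneity_tol` **and** the two region means agree
within `homogeneity_tol`. The second condition matters: a region of
thousands of body pixels can absorb an isolated coating pixel with
negligible effect on its standard deviation, so a pure merged-std criterion
silently eats the minority side of boundary blocks. Requiring
mean-similarity is the precise sense in which the merge joins "similar"
neighbors. Passes repeat until no merge applies.

### Threshold and labeling

Region means are thresholded by Otsu's criterion computed on the
pixel-weighted region-mean histogram (256 bins over the sample range).
When the criterion is flat across a span of bins — the normal case for a
well-separated bimodal histogram, whose valley is empty — the plateau
midpoint is taken; taking the first maximizing bin would put the threshold
against one mode and is numerically unstable besides. The side of the
threshold with the higher mean a\* is labeled body (red dominance); this
keys the labels to color, not to region size, so swapping body and coating
colors swaps the masks.

Two per-pixel fallbacks implement the chrominance-threshold component for
thin or overlapping coating:

* regions whose mean lies within `homogeneity_tol` of the threshold are
  relabeled pixel by pixel against the threshold (their region mean is
  ambiguous by construction);
* any pixel whose own chrominance lies beyond the threshold by more than
  `homogeneity_tol` on the side *opposite* its region's label is flipped.

The second rule recovers pixels that the merge phase attached to the wrong
side while never touching pixels whose evidence is weak, so it does not
inject salt-and-pepper noise at realistic noise levels. With zero texture
and noise the combination is exact (IoU = 1 against ground truth); at the
default noise settings measured IoU exceeds 0.999.

If the region-mean histogram is single-mode (single region, an empty side
of the threshold, or modes closer than `homogeneity_tol`), the entire
tongue is labeled body and a warning is raised — the correct reading of a
coating-free tongue.

## Color features

Per region, the package reports mean R, G, B (8-bit scale), H, S, I and
L\*, a\*, b\*. The mean is taken in RGB first and the single mean color is
then transformed (`per_pixel = TRUE` selects transform-then-average
instead). Mean-then-transform matches the convention of reporting one
representative color per region; the two orders differ in general because
the transforms are nonlinear.

HSI uses the arccos formulation with hue reflected to (180°, 360°) when
B > G; achromatic colors take H = 0 and S = 0 by convention (black
included). CIELAB assumes sRGB primaries and the D65 white point — the
capture illuminant of standardized tongue instruments is close to D65 —
with the BT.709 6-digit coefficient matrix, matching widely used reference
implementations to better than 10⁻³.

## Texture features

Gray level is the rounded BT.601 luminance (0.299 R + 0.587 G + 0.114 B).
For displacement δ, `p(i)` is the normalized histogram of
|g(x) − g(x+δ)| over all pixel pairs with both endpoints in the region
mask. The four statistics are CON = Σ i²p(i), ASM = Σ p(i)², ENT =
−Σ p(i) log₂ p(i) (bits; base configurable), MEAN = Σ i·p(i), averaged
over the two axial unit displacements δ ∈ {(0,1), (1,0)} by default. The
choices of luminance weights, displacement set and entropy base are this
package's (the statistics are classical; their parameterization varies
across the literature). Absolute differences make all four statistics
invariant to constant gray shifts, which the tests assert.

## Preprocessing

**SMOTE.** Synthetic minority rows are `x + u (x_nn − x)`, `u ~ U(0,1)`,
with `x_nn` one of `x`'s k = 5 nearest minority neighbors (k = 5 is the
canonical SMOTE default). Distances are computed on a min–max-scaled copy
so no feature dominates; interpolation happens in raw feature space. A
non-integer oversampling rate is handled exactly: with `n` minority rows
and `s` synthetic rows required, every minority row seeds `⌊s/n⌋`
synthetics and a seeded random subset of `s mod n` rows seeds one more —
a 296-vs-531 table equalizes to exactly 531/531. Binary covariates
(gender) are rounded on synthetic rows, a documented distortion of the
interpolation. SMOTE runs on training rows only, after the train/test
split; balancing before the split would leak synthetic copies of training
points into the test set.

**Scaling.** Per-feature affine map of the training min/max to [−1, 1];
constant features map to 0; test values outside the training range
extrapolate beyond ±1 (no clipping, so the map stays affine).

**PCA.** Centered (not re-scaled — features are already on [−1, 1]) with
the smallest component count whose cumulative explained-variance ratio
reaches `retain` (default 0.95). With fewer samples than features the
count caps at the data rank with a warning. Fitting is train-only;
projection is centering plus multiplication by the retained components.

The full feature vector has 29 columns: 3 covariates + 2 regions × 9 color
+ 2 regions × 4 texture. When an image has no coating, its coating
features are missing and are imputed with training-set means before
scaling, keeping dimensionality fixed. Feature subsets are configurable.

## GA-SVM

The classifier is a C-classification RBF SVM, K(x,y) = exp(−g‖x−y‖²). The
quadratic program is delegated to `e1071::svm` (libsvm); this package
contributes the surrounding search and validation machinery. The
chromosome is (log₂ c, log₂ g) with bounds log₂ c ∈ [−5, 15],
log₂ g ∈ [−15, 3] — the standard soft-margin RBF search box. Fitness is
the mean held-out accuracy of stratified 10-fold cross-validation, with
the fold assignment drawn once per run from the seed and fixed across all
evaluations, so fitness is a deterministic function of the chromosome and
can be cached.

GA settings: population 20 evolved for 100 generations; tournament
selection of size 2; uniform crossover with probability 0.7; per-gene
Gaussian mutation with probability 0.1 and σ = 0.5 log₂ units, clipped to
the bounds; elitism of the single best individual. Population size and
generation count are the method's stated operating point; the operator
suite is a standard default set, all configurable through `ga_config()`.
The returned optimum is the best chromosome *ever evaluated*, so the
best-so-far trace is non-decreasing by construction; the characteristic
rising-from-a-plateau fitness curve is reproduced on synthetic tasks. On
those tasks the GA matches an 8×8 log-grid search oracle within 0.02
cross-validated accuracy at a comparable evaluation budget.

## Evaluation

The split is stratified 80/20 by default: each class contributes
`round(0.8 · n_class)` training rows (R's round-half-to-even), drawn by
seeded permutation. Metrics use label 1 (the disease-analog class) as
positive: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). The ROC
steps at every distinct score with ties stepping simultaneously; the
trapezoid AUC then equals the tie-corrected Mann–Whitney pair statistic
exactly, which the tests assert to 10⁻¹². ROC curves are produced for each
class as positive in turn; for a binary problem the two curves are
reflections of one another through (0.5, 0.5).

Baselines run on identical train/test tables: k-NN (k = 5; score =
positive-neighbor fraction), Gaussian naive Bayes (score = posterior),
and a single-hidden-layer backpropagation network (10 sigmoid units,
entropy loss; score = output activation). Their hyperparameters are
conventional defaults, configurable. The GA-SVM scores are its decision
values, oriented so positive means class 1. Whether a study reports a
single split or an average over repeated splits is a design choice; a
single seeded split is the default here, and repeated runs with different
seeds are cheap.

## The synthetic study

`study_spec()` defines the default end-to-end experiment: 120 subjects
(45 disease-analog, 75 control — preserving a minority fraction close to a
296/531-style clinical cohort at desk scale), 64×64 images, body color
(180,120,120) and coating color (210,200,170) with per-subject color
jitter (σ = 4 per channel), texture σ = 5, noise σ = 3, coating fraction
0.3 ± 0.03. The disease-analog class shifts the body color by
(+15, −10, −5), the coating by (−8, 0, +10), the coating fraction by
+0.1, age by +6 years and BMI by +3 kg/m². These shifts are set so that an
oracle classifier on the true features is comfortably above 90 % accuracy:
the end-to-end run validates the pipeline machinery (segmentation →
features → preprocessing → GA-SVM), and a borderline-separable cohort
would confound machinery errors with irreducible statistical noise at the
24-subject test-set scale. A null configuration (all shifts zero) is used
in the tests to confirm the opposite: chance-level AUC when no signal
exists.

What the generator does *not* emulate: photorealistic tongue appearance,
illumination and color-temperature variation, specular highlights, cracks
and papillae structure, or correlated (non-Gaussian) texture. Passing
tests therefore establish correctness of the computation, not clinical
performance; the clinical numbers of any particular cohort are outside
what synthetic fixtures can reproduce.

## Numerical choices and degenerate inputs

* Otsu plateau → midpoint bin (see above); degenerate histograms (a single
  value) return that value.
* Population (not sample) standard deviations in the split/merge phases;
  block statistics via summed-area tables in O(1) per block.
* `coating_fraction` 0 and 1 short-circuit to empty/full coating; the
  coating ellipse scale is otherwise solved by 48 bisection steps on the
  pixel grid (the achieved fraction is exact only up to pixelization,
  within 0.05 at the default size).
* Empty regions yield NA features flagged `missing`, imputed downstream.
* Black input to HSI: S = 0, H = 0 by convention.
* Decision-value orientation of the SVM is normalized after training so
  that positive always means class 1, regardless of the label order seen
  by the solver.
* All stochastic stages draw their seeds from one pipeline seed;
  `with_seed()` restores the caller's RNG state, so library calls never
  perturb user randomness. Reports are written with full double precision
  (`digits = NA`), making byte-identical reruns a testable contract.

## Problem sizes used by the test-suite and acceptance runs

Unit tests run on 16–64 px fixtures and feature tables of 30–400 rows. The
full-scale checks use the 120-image study, a 296/531 SMOTE table, a
300-row GA task (population 20, 100 generations, 10-fold CV) against an
8×8 grid-search oracle, and 100 random score vectors for the AUC/Mann–
Whitney identity. These sizes were chosen as the smallest at which each
property is meaningfully exercised.

## Known limitations

* The segmenter assumes exactly two chrominance populations; mottled
  coatings (grey + yellow) would need a multi-way extension.
* SMOTE interpolation treats all features as continuous; rounding binary
  covariates is a crude repair.
* The BP-NN baseline uses full-batch BFGS-style training as provided by
  its underlying library rather than literal online backpropagation.
* GA fitness caching assumes exact chromosome equality; continuous
  mutation makes cache hits common only through elitism and
  crossover-free reproduction, so runtime is dominated by unique
  cross-validation evaluations.
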