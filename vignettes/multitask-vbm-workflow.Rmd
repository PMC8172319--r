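---
title: "Multitask 3D CNNs for VBM volumes: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask 3D CNNs for VBM volumes: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Voxel-based morphometry (VBM) turns a structural MRI scan into a pair of
co-registered 3D tissue-density maps — gray matter (GM) and white matter
(WM) — on a common stereotactic grid. During childhood and adolescence these
maps change in a highly structured way (myelination increases WM, synaptic
pruning reduces GM), with different trajectories per gender, and possibly
with subtle alterations in neurodevelopmental conditions such as ASD and
ADHD. `vbmnet` implements a complete, testable workflow for learning those
patterns with a single multitask 3D convolutional network that predicts
**age** (regression), **gender** and **diagnostic status** (binary
classification) jointly, and for asking the trained network *where it
looked*, via SmoothGrad attention maps intersected with a brain atlas.

Because the real inputs for such a study are tens of gigabytes of
downloaded, SPM-preprocessed scans, the package is built around a synthetic
cohort generator that emulates the *contract* of VBM outputs (values in
[0, 1] inside the brain, exactly −1 outside, spatial smoothness, a shared
grid and atlas) while letting the analyst inject known regional effects.
Every downstream stage — I/O, folds, training, checkpointing, metrics,
attribution — can therefore be validated against ground truth.

## The model

The network body is a sequence of `conv_blocks` identical blocks:

    batch-norm  →  3×3×3 convolution (ReLU, same padding)  →  3×3×3 max-pool, stride 2

followed by flatten → dropout (rate 0.5) → a shared dense layer (ReLU).
Three heads branch from the shared representation, each

    dense (ReLU)  →  batch-norm  →  dense(1)

with a sigmoid output for gender and diagnosis and a linear output for age.
Batch normalisation placed *before* each convolution and before each head's
output layer follows the architecture this package reimplements, taken
literally. An L2 penalty (coefficient `1e-3`) applies to every convolutional
and dense kernel; biases and batch-norm parameters are exempt.

The joint objective is the weighted sum of per-task batch means,

$$L = w_1\,\mathrm{MSE}(y_\text{age}, \hat y_\text{age})
    + w_2\,\mathrm{BCE}(y_\text{gender}, \hat y_\text{gender})
    + w_3\,\mathrm{BCE}(y_\text{diag}, \hat y_\text{diag}),$$

with all weights 1 by default (deliberately untuned). Because the MSE term
lives on squared years it dominates the raw loss scale; that asymmetry is a
property of the method, not a bug, and the per-task checkpointing below is
what makes the classification heads usable anyway.

Encodings, stated once and used everywhere: gender positive class = female
(1); diagnosis positive class = disorder (1).

### The compute engine

No deep-learning framework is involved: the forward pass, backpropagation
(including through batch-norm and max-pooling), Adam, dropout and the
input-gradient computation for saliency are implemented in this package,
with RcppArmadillo kernels. Convolutions are GEMM-based (im2col with a
transposed, cache-friendly layout); arithmetic is single precision with
losses accumulated in double precision. Cross-entropy probabilities are
clamped to $[10^{-7}, 1-10^{-7}]$; batch-norm uses $\varepsilon = 10^{-5}$
and running-statistics momentum 0.9. Inference (and hence every metric and
attention map) is deterministic; training is deterministic on a fixed-thread
BLAS, with a documented tolerance of $10^{-3}$ relative on per-epoch losses
for multi-threaded backends.

## Training protocol

* **Optimiser**: Adam, learning rate $10^{-3}$, moment decays 0.9/0.999,
  batch size 32, up to 1000 epochs by default. Batches are plain reshuffles
  of the training set (seed derived from `(run seed, epoch)`); classes are
  *not* balanced at the batch level.
* **Custom early stopping**: training stops once `patience` (default 75)
  consecutive epochs pass in which *none* of the three validation losses
  (age MSE, gender BCE, diagnosis BCE) strictly improves its running
  minimum. The counter is global — any task improving resets it — with a
  per-task variant behind `patience_mode = "per_task"`. "Improvement" is a
  strict decrease with min-delta 0.
* **Per-task checkpointing**: at every epoch end, each task whose validation
  loss hits a new minimum has the full parameter set snapshotted. One
  training round therefore yields three model versions, one per task.
  Restoring a checkpoint and rescoring the validation set reproduces the
  recorded loss exactly (parameters round-trip bit-exactly through double
  precision).
* **Age output initialisation**: the age head's output bias starts at the
  training-set mean age. At the short training budgets used for validation
  (tens of epochs, a handful of batches per epoch) Adam's per-step movement
  is bounded by roughly the learning rate, so a zero-initialised output
  could never traverse the ~13-year offset; centring removes that constant
  from the optimisation without constraining the output range. No other
  target transformation is applied — the loss stays MSE in years.

## Cross-validation scheme

`make_folds()` implements the custom stratified k-fold: subjects are
stratified by diagnosis only, shuffled, and dealt round-robin into k
partitions. In round *r*, partition *r* is the test set; walking cyclically
from *r + 1*, the first *k − 2* partitions form the training set and the
last one the validation set. Every subject appears in exactly one test set;
per-class partition counts are within one of exact proportionality; the
cyclic order (rather than a fresh shuffle per round) makes every round
reconstructible from the single seed. Test partitions influence nothing
until their round's training has finished — operating points are chosen on
validation data and applied unchanged to test data.

## Metrics and operating points

Regression: MAE, Pearson's r with the exact t-transform p-value (n − 2 df),
and prediction R² computed against the evaluation-set mean (so it can be
negative). Zero-variance targets or constant predictions are *flagged*, not
silently zeroed. Classification: precision, recall, F1 and AUC-ROC, the
latter via midranks (exact under ties, equal to the pairwise
probability-of-correct-ranking). The classification threshold is selected on
validation data as the cutoff maximising the harmonic mean of sensitivity
and specificity, scanning the midpoints between consecutive distinct scores
plus one candidate below and one above — a finite set that exhausts all
achievable confusion tables; ties go to the lowest threshold.

`confound_check()` quantifies how much gender/age signal total brain volume
alone carries (AUC of the volume scalar against gender, Pearson r against
age). Its default statistic counts in-brain voxels with positive density;
on synthetic cohorts sharing one brain mask that count is constant by
construction, so the density-sum variant (`statistic = "sum"`) is the
informative one there and is what the null-cohort benchmark uses.

## SmoothGrad attribution and ROI ranking

For a chosen task, the input is perturbed `n_samples = 5` times with
zero-mean Gaussian noise of standard deviation `0.20 × (max − min)` of the
in-brain input values (the SmoothGrad convention for "20% noise"); the
gradient of that task's output alone — the other heads are excluded from the
differentiated scalar — is taken with respect to the input in inference
mode; absolute values are used (gradient sign in tissue-density space is
context-dependent); the two tissue channels are collapsed by voxelwise mean
(max behind a flag); and the per-perturbation maps are averaged. Background
voxels are zeroed.

Aggregation follows a normalise-then-average discipline: per fold, the maps
of the fold's test examples are averaged voxelwise; each fold average is
min–max normalised to [0, 1] over in-brain voxels (after background
masking); the normalised fold maps are averaged into one map per task. ROI
ranking intersects that map with the labelled atlas using the per-ROI
*mean* attention (so large ROIs are not automatically favoured; sum behind a
flag), sorting descending with ties to the lower ROI id. A
nearest-neighbour resampler is provided for atlases on a different grid; it
is an index-space stand-in, not registration.

## The synthetic generator

What it emulates: two-channel tissue-density volumes on a common grid with
an ellipsoidal brain, baseline densities 0.6 (GM) and 0.5 (WM), regional
effects coupled to phenotypes, Gaussian smoothing (σ = 1.5 voxels, standing
in for the 8 mm FWHM of real VBM), additive voxel noise (SD 0.05), clipping
to [0, 1], background exactly −1, ages uniform on 6–20 years, 37% female and
39% diagnosed (the demographic envelope of a paediatric ADHD-type sample).
Baselines and effect-size guidance were chosen so magnitudes of 0.01–0.05
neither clip nor vanish under the noise. Each subject consumes an RNG
substream derived from `(seed, subject index)`, so cohorts are bit-for-bit
reproducible, including under partial regeneration. Atlas ROIs are a
Voronoi tessellation of the brain interior around randomly placed seeds —
contiguous blobs, like (but much simpler than) an anatomical parcellation.

What it does *not* emulate — and therefore what passing tests do not show
about real data: scanner/site effects, cortical folding and tissue-boundary
geometry, registration error, inter-subject brain-size variation (a single
common mask is used), non-uniform age distributions, and label noise. The
generator demonstrates that the machinery recovers structure it was given;
it cannot certify performance on downloaded cohorts.

## Validation studies and problem sizes

Two exported studies define the package's empirical checks (run by the test
suite and by `scripts/acceptance.R`):

```{r}
library(vbmnet)
rec <- recovery_benchmark(seeds = 1:10)  # injected-effect recovery
nul <- null_benchmark(seeds = 1:5)       # effect-free control
```

`recovery_benchmark()` draws, per seed, a 400-subject cohort on a 32³ grid
with an age slope of −0.02 density/year in one ROI and a gender offset of
0.04 in another, trains rounds of the k = 3 scheme with a 2-block network
(filters 4 and 8, dense width 32) for at most 40 epochs each (patience 12,
batch size 8 — about 700 optimizer steps per round, the desk-scale analogue
of full-scale runs of thousands of steps), selects the best checkpoint per
task **across the trained rounds** by validation loss — the same
best-across-rounds selection the full workflow applies — and scores it on
its own round's untouched test partition (~134 subjects). Success per
replicate: age test MAE below 0.6× the predict-the-mean baseline, gender
test AUC of at least 0.8, and each injected ROI inside the attribution top
3 for its task.

Why across rounds: the joint objective is dominated by the age MSE term, so
the gender head starts on a loss plateau and needs a favourable
split/initialisation to escape it within the epoch budget (observed
trajectories show a flat validation BCE near ln 2 for tens of epochs, then
a rapid descent). The age task converges in essentially every round;
gender converges in a clear majority of rounds, and selecting over three
rounds makes the study's verdict reflect the method rather than one round's
optimization luck. As a pure compute saving, later rounds are trained only
while the best gender validation loss is still at chance level — a
validation-only decision that never touches test data.

`null_benchmark()` repeats the protocol on effect-free 200-subject cohorts
(15 epochs, patience 5): classification AUCs should sit in the chance band,
the age prediction R² should not rise meaningfully above zero, and the
volume confound check should find nothing. Because one test partition of
~66 subjects leaves a null AUC a standard error of ~0.07, the chance band is
assessed on the across-seed mean.

These sizes — 32³ grids, hundreds of subjects, tens of epochs — are the
package's chosen validation scale; the same code paths run unchanged at
121×145×121 → 128³ with the default 4-block model for full-scale data.

## Numerical choices and degenerate inputs

* Pad/trim to a cube is centred, pads with −1, puts the odd voxel on the
  high side, and refuses to trim any plane containing an in-brain voxel
  (data-loss error). It conserves the multiset of in-brain values exactly.
* Pooling uses ceil(n/2) output sizes (SAME padding; the extra plane of
  padding goes to the high side), so a 32³ input traces 32 → 16 → 8.
* Record files (`write_records()`) are a versioned binary container —
  magic `VBNREC`, format version, per-record JSON header plus float32
  payload — with streaming reads and truncation errors that name the
  offending record.
* Degenerate metric inputs (one class only, zero variance, all-equal
  scores) raise typed errors, flags, or warnings; nothing is silently
  coerced to 0.
* Fold-map normalisation of a constant map is skipped with a warning
  rather than dividing by zero. One real way this arises: gradients are
  taken through the head's sigmoid, so a fully saturated classifier
  (probabilities at the clamp) has vanishing output gradients and produces
  an all-zero attention map — surfaced as that warning, never silently
  rescaled.

## Known limitations

The diagnosis task on realistic effect sizes performs near chance — as it
does at full scale in the literature this workflow follows — so its head is
exercised for mechanics (loss, checkpointing, thresholding) rather than
accuracy. Absolute-gradient attribution on a multitask model inherits a
known caveat: the shared body's strongest feature (here, the age-coupled
region) can dominate the gradient magnitudes of *every* head, so a weaker
task's map may under-rank its own region even when that task classifies
perfectly; interpreting per-task maps therefore always requires the
across-replicate view the recovery study takes, not a single map. The
engine is CPU-only and single-node. The atlas resampler is
nearest-neighbour in index space. Loss weights are fixed at 1; tuning them,
nested hyperparameter search, and three-way disorder classification are out
of scope.
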