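---
title: "coroflow: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coroflow: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

coroflow assesses whether a coronary artery stenosis is functionally
significant — invasive fractional flow reserve (FFR) at or below 0.8 —
from coronary CT angiography (CCTA). This vignette explains the models the
package implements, the assumptions behind them, the parameters that
matter, and the numerical decisions taken where the design was genuinely
open. Everything described here is exercised by the package's test suite
on synthetic vessel phantoms; no empirical claim is made beyond what those
tests compute.

## Pipeline overview

The pipeline takes a CT volume (HU intensities, physical spacing) and a
labeled coronary centerline tree, and produces per-artery predictions:

1. **MPR reconstruction** (`resampleCenterline()`, `reconstructMPR()`):
   the artery is straightened into a stack of 127 x 127 cross-sections
   with 0.1 mm in-plane pixels, one slice every 0.5 mm along the
   centerline, sampled by trilinear interpolation.
2. **Artery characterization** (`buildCharacterizer()`,
   `characterizeArtery()`): a 2D CNN regresses, for every cross-section,
   the lumen area (mm^2), the mean lumen attenuation (HU) and the calcium
   area (mm^2) from a stack of three neighbouring slices.
3. **Tree characteristics** (`extractTreeCharacteristics()`): two binary
   per-slice series from the centerline tree — a bifurcation indicator
   (mapped node has two or more children) and a main-branch indicator
   (label in LM/LAD/LCX/RCA).
4. **Stenosis assessment** (`buildStenosisNet()`, `predictStenosis()`): a
   1D convolution + transformer network over the five characteristic
   series with two heads: a regression head that sums non-negative
   per-position pressure drops into `FFR = 1 - sum(drops)`, and a
   classification head that outputs a significance probability.
5. **Merging and ensembling** (`pseudoProbability()`, `mergeOutputs()`,
   `crossvalTrain()`, `ensemblePredict()`): the regressed FFR is mapped
   to a pseudo-probability by linearly rescaling the window
   `[0.6, 1.0]` around the 0.8 threshold (`p = 0.5 - (FFR - 0.8)/0.4`,
   saturating at 1 below 0.6), averaged with the classification
   probability, and averaged again across a patient-level 10-fold
   cross-validation ensemble whose member spread (population sd) is the
   prediction uncertainty.
6. **Evaluation** (`computeMetrics()`, `patientLevel()`,
   `aucPermutationTest()`, `referralSimulation()`, `ablationHarness()`):
   Mann-Whitney AUC with ties counted one half, operating-point metrics at
   a probability threshold of 0.5 (FFR threshold 0.8), max-pooling
   aggregation to patients, paired sign-flip permutation testing of AUC
   differences, and an uncertainty-based referral simulation.

## MPR geometry

Two conventions are unspecified in the general description of straightened
MPRs and had to be fixed:

* **In-plane orientation.** Frames are rotation-minimizing
  (parallel-transport), computed with the double-reflection method and
  initialized from a fixed arbitrary normal at the ostium. This avoids the
  torsion artifacts a Frenet frame would introduce at inflection points;
  consecutive in-plane axes rotate by well under 10 degrees for the
  curvature range of the phantoms, which matters because the
  characterization network sees stacks of three consecutive slices.
* **Tangents** are central differences of the resampled points, one-sided
  at the artery ends.

Centerline resampling walks the raw polyline emitting points at exactly
0.5 mm Euclidean distance (sphere-polyline stepping), so consecutive-point
spacing is exact to machine precision even on curved paths. Coordinates
are physical mm, volume indexing is 0-based inside the interpolation
arithmetic, and MPR pixel (64, 64) (1-based) is the centerline point.
Samples outside the volume are filled with -1024 HU and counted; an artery
with more than 5% filled samples is rejected, mirroring a field-of-view
inclusion rule.

MPR intensities are normalized to zero mean and unit variance with
statistics pooled over all voxels of the training corpus
(`fitIntensityStats()`); the same statistics are applied unchanged at test
time and persist with the model.

## The characterization network

Four blocks of two 3 x 3 convolutions (16 filters) with batch
normalization and ReLU, each block followed by 2 x 2 max pooling
(127 -> 63 -> 31 -> 15 -> 7), then three separate heads, each global
average pooling plus one linear unit. Decisions taken where the
architecture description left room:

* **Pooling type**: max pooling, the standard choice for edge-dominated
  regression targets like lumen boundaries.
* **Head structure**: global-average pooling with a single linear unit per
  head — the most parsimonious reading of "three separate output heads",
  and deliberately low-parameter against overfitting.
* **Target normalization**: targets are standardized over the training
  slices and de-normalized at output. This keeps the three loss terms
  comparable so that the fixed 0.1 weight on the attenuation MAE term has
  the intended effect of balancing magnitudes.

The training loss is `MAE(lumen) + 0.1 * MAE(attenuation) + MAE(calcium)`
with AdamW. The reference schedule (learning rate 1e-5, batch 512, 800
epochs) is the config default; it presumes tens of thousands of training
cross-sections. The package's own test-scale runs use the standard
compensation for a much smaller budget — a larger learning rate (1e-3),
small batches and few epochs — which is a schedule choice, not an
architecture change.

## The stenosis-assessment network

Inputs are the five per-slice series, normalized to zero mean and unit
variance with statistics pooled over the training arteries
(`fitCharacteristicStats()`; a zero-variance characteristic — e.g. an
all-zero calcium toy corpus — keeps sd 1 with a warning). Lumen area and
attenuation additionally pass through a percentage-difference transform
`d[i] = (x[i] - x[i-1]) / (|x[i-1]| + 1e-6)` computed on the raw series
(the transform is scale-free, so raw input keeps the epsilon guard
meaningful; `d[1] = 0`).

Dataflow: the two difference series feed separate two-layer convolutional
pre-encoders (LeakyReLU between the layers); the encodings are
concatenated with the three remaining normalized series (35 channels);
average pooling with kernel 4 reduces the length; two convolutions with
dilations 1 and 2 follow, each with LeakyReLU, instance normalization
(over the sequence dimension, per channel) and dropout 0.5; the
pooled-resolution normalized lumen/attenuation series are concatenated
back in (18 channels), linearly projected to width 16 and passed through
one transformer encoder layer. All convolutions have kernel 3 and zero
padding.

Open points fixed here:

* **Transformer internals**: 2 heads, width 16, feed-forward width 32,
  post-norm residual layout, no positional encoding. The layer is
  motivated purely by its global receptive field, and the sum-pooling
  classification head stays order-aware through its contiguous bins, so a
  positional code adds parameters without a clear gain. The 18-channel
  concatenation is mapped to the 16-channel transformer width by a learned
  linear projection.
* **Length alignment** of the lumen/attenuation bypass: average pooling
  with kernel 4, matching the encoder's pooling factor.
* **Adaptive sum pooling**: 5 contiguous near-equal bins; when the pooled
  length is not divisible by 5 the remainder goes to the proximal bins;
  bins beyond a very short artery stay empty (zero sums).
* **Regression head** = two conv/LeakyReLU/instance-norm/dropout stages,
  then a single-filter convolution with ReLU: per-position drops are
  non-negative by construction, so `FFR = 1 - sum(masked drops)` can never
  exceed 1 — an architectural guarantee, tested for arbitrary weights.
  The final drop convolution is initialized near zero so the initial drop
  sum (hence the starting FFR) is close to 1 regardless of artery length;
  a small positive scale keeps its ReLU from starting dead.
* **Classification head** consumes the full post-transformer feature map
  (sum-pool to 5 bins, flatten, two dense/LeakyReLU/dropout stages, a
  final dense unit with sigmoid).
* **Measurement mask**: drops distal to the assumed pressure-wire
  position (10 mm = 20 slices beyond the annotated lesion; without a
  lesion, the most distal slice with lumen area above 2 mm^2) are
  excluded from the sum. At the pooled resolution a position is kept if
  any of its four source slices is kept — conservative inclusion of the
  measurement location.
* **Dropout** (probability 0.5) is applied after every
  convolution+normalization stage and inside the dense classification
  stack, but not inside the transformer layer, whose internals are
  treated as a standard encoder block.
* **Class weighting**: the binary cross entropy is unweighted; nothing in
  the reference settings suggests prevalence reweighting at 0.42.

Training minimizes `MSE(FFR) + BCE(probability)` with equal weights, one
artery per forward pass (lengths vary), gradients accumulated over 8
arteries per AdamW update, and a triangular cyclic learning rate between
5e-4 and 1e-5 over a 40-epoch period. Weight decay is not specified by the
reference settings; the package default is 1e-3, chosen on development
phantoms before the acceptance experiments were run. Dropout is disabled
at inference, so predictions are deterministic for fixed weights.

One subtlety the test suite makes explicit: besides self-attention, the
*instance-norm statistics* also couple every sequence position (a
perturbation anywhere moves each channel's mean and variance). A
locality test of the measurement mask therefore has to ablate both
pathways; the package provides inference-only diagnostic flags for this,
and separately verifies on the unablated network that masked positions
contribute exactly zero to the drop sum.

## Merging, ensembling, uncertainty

The pseudo-probability transform is piecewise linear, continuous at 0.6,
and calibrated so that thresholding it at 0.5 is identical to
thresholding the FFR at 0.8. Member predictions are merged (arithmetic
mean of classification and pseudo-probability) before ensemble averaging;
with arithmetic means the two orders coincide, which the tests assert.
Uncertainty is the population (not sample) standard deviation across the
10 members — the ensemble is a fixed set, not a sample from a larger
population. Cross-validation folds are drawn at the patient level so no
patient contributes to both a member's training set and its validation
fold; all members share the normalization statistics fitted on the full
development set, which is what makes them ensemble-able.

The referral simulation replaces (or removes) the `ceiling(fraction * n)`
cases with the highest uncertainty by their reference outcome and
recomputes the metrics; ties in uncertainty break by case id for
determinism. Ranking uses the merged-probability spread by default, with
the FFR spread as an alternative. The permutation test swaps the two
models' scores per case with probability one half (the standard paired
sign-flip scheme for comparing AUCs on the same cases) and applies
add-one smoothing so p is never exactly zero.

## The synthetic phantom cohort

No clinical data ships with the package; every stage is exercised on
synthetic phantoms whose distributions are explicit artifact choices:

* **Geometry**: a tube along a smooth random centerline (spline
  perturbation bounded to +-2 mm so the tube cannot self-intersect),
  baseline radius 1.1-1.6 mm, length 40-80 mm in cohorts; focal stenoses
  are cosine bumps in fractional area reduction (`r(s) =
  r0 * sqrt(1 - reduction(s))`); calcified plaque occupies an angular arc
  of a 0.8 mm shell abutting the lumen. Calcium placement is independent
  of the stenoses: anatomical calcium burden is an imperfect marker of
  functional significance, and tying the two together would let a
  lumen-blind model shortcut the task.
* **Intensities**: lumen 400 HU, soft tissue 50 HU, calcium 800 HU,
  Gaussian noise with sd 20 HU — inside typical CCTA acquisition ranges.
  Default voxel spacing is 0.3 mm isotropic, inside the reported
  reconstruction range of clinical CCTA.
* **Partial volume**: masks (and the HU mixing at boundaries) are
  fractional coverage values with a one-voxel linear ramp across the
  surface rather than 0/1 indicators. CT is band-limited, so this is the
  physical choice; it also makes resampled mask areas nearly unbiased
  (binarizing voxel-center indicators at clinical voxel sizes biases
  areas by several percent at small radii).
* **Ground-truth FFR** comes from a deliberately simple hemodynamic
  model: a serial Poiseuille-type viscous term (`Q * c * sum(l / A^2)`)
  plus one quadratic separation term
  `k * Q^2 * max(0, 1/A_min - 1/A_ref)^2` with a *fixed* reference
  caliber `A_ref = 3 mm^2`. A single global-minimum term (rather than one
  term per detected lesion with a profile-derived reference) is what
  makes the model provably monotone under pointwise area reduction —
  with a profile-derived reference, lowering the profile maximum can
  lower the separation term and raise the FFR, and merging two lesions
  can shrink a sum of squared terms. The constants are fixed by two
  anchors, not fitted to any data: an unobstructed 3 mm^2 artery of
  100 mm yields FFR 0.98, and a 70%-area stenosis of 10 mm length in that
  artery yields FFR 0.70 (`calibrateFFRModel()` re-derives them by
  root-finding; the frozen values are in `ffrModelParams()`).
* **Cohorts** (`generateCohort()`): 1-3 arteries per patient; stenosis
  severities are rejection-sampled so the fraction of FFR-positive
  arteries matches the requested prevalence (default 0.42, a typical
  development prevalence for FFR cohorts). Profile observation noise
  (lumen sd 0.2 mm^2, attenuation sd 15 HU, calcium sd 0.15 mm^2)
  emulates characterization error at magnitudes comparable to what the
  phantom-trained characterizer actually achieves.

What the phantoms deliberately do **not** model: anatomically realistic
cardiac background, motion or step-and-shoot artifacts, contrast-bolus
dynamics, transluminal attenuation gradients (phantom attenuation is
constant along the vessel, so the attenuation channel carries no
hemodynamic signal), diffuse disease, and serial-lesion interaction
beyond the additive viscous term. Passing tests on phantoms therefore
demonstrates that the pipeline's machinery is correct and trainable —
not that it reaches any particular clinical performance.

## Problem sizes used by the test suite

The test suite trains real models at sizes chosen to make the experiments
informative yet quick to reproduce:

* **Characterizer parameter recovery**: 30 phantom arteries of 22-30 mm
  (24 train / 6 held out), analytic ground truth as targets, training on
  every other cross-section for 4 epochs at learning rate 1e-3, batch 8.
  The held-out lumen-area relative MAE lands well under the 15%
  acceptance bound (around 6% in development runs).
* **End-to-end discrimination**: per seed, a development cohort of 50
  patients (~100 arteries, prevalence 0.42) trains a 10-fold
  cross-validation ensemble (50 epochs per member); the 10-member
  ensemble is evaluated on a held-out cohort of 40 patients
  (~80 arteries). Averaged over 3 seeds the ensemble's merged-probability
  AUC must reach at least 0.85 (development runs: ~0.94). The ablation
  comparison trains single networks with all channels versus with the
  lumen channel zeroed (at train and test time) and requires the
  lumen-blind model to rank strictly lower — on these phantoms the FFR
  label is lumen-driven, so this is the expected ordering.

## Known limitations

* The hand-written training loop is single-threaded; the reference-scale
  schedules (800 / 150 epochs on hundreds of arteries) are supported but
  slow, and the package is intended for method development and synthetic
  validation rather than production training.
* The regression head's FFR magnitudes on small phantom cohorts are
  compressed toward the cohort mean even when its ranking (AUC) is
  strong; the merged probability compensates for this by design.
* Phantom attenuation carries no signal, so the attenuation channel's
  contribution cannot be assessed on phantoms — only its plumbing.
* `simulateFFR()` is a labeling device for phantoms, not a hemodynamic
  simulator; its constants have no physiological meaning beyond the two
  calibration anchors.
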