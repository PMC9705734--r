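---
title: "PERCIST-guided tissue classification and lesion detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PERCIST-guided tissue classification and lesion detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percistnet)
```

## The problem

[18F]FDG PET/CT is the workhorse of metabolic oncologic imaging: avid tissue
— tumours, but also brain, myocardium, kidneys, bladder, brown fat — takes up
the glucose analogue, and quantification in SUL (standardized uptake value
normalised by lean body mass) makes uptake comparable across patients and
scanners. PERCIST v1.0 anchors all quantification to the patient's own liver:
a 3 cm^3 spherical reference VOI is placed in hepatic parenchyma, and all
measurability thresholds are linear functions of the liver mean and standard
deviation.

`percistnet` implements an automated workflow for classifying every voxel of
a breast-cancer FDG PET/CT study into 16 tissue classes and detecting disease
(primary lesions plus nodal involvement), combining:

1. **threshold-based annotation** — PERCIST thresholds turn the PET volume
   into candidate segmentations that a reader (or, on phantoms, the ground
   truth) classifies into tissue classes, producing voxel-complete label maps;
2. **a 2D multi-class U-Net** trained on those label maps, slice by
   transaxial slice, with two input channels (PET, CT);
3. **PERCIST post-processing** of the network output, which re-derives the
   liver statistics from the *predicted* reference region and clears every
   tissue annotation below the follow-up threshold.

Because the clinical trial images behind the original workflow are not
redistributable, the package ships a synthetic phantom generator that
reproduces the statistical structure the workflow relies on; every stage is
exercised end to end on phantoms in the test suite.

## Thresholds and annotation

Three liver-referenced thresholds are used, all in SUL:

* baseline assessment: $T_b = 1.5\,\mu_L + 2\,\sigma_L$
* reference (growth): $T_r = 1.0\,\mu_L - 2\,\sigma_L$
* follow-up assessment: $T_f = 1.0\,\mu_L + 2\,\sigma_L$

with $\mu_L, \sigma_L$ the liver VOI mean and SD. For any valid statistics
$T_r \le T_f < T_b$. SUL conversion uses the James lean-body-mass equations
(male $1.10W - 128(W/H)^2$, female $1.07W - 148(W/H)^2$) and decay-corrects
the injected dose to scan start with the 18F half-life (109.77 min). The SD
convention is the population SD (divide by $n$): the sampled voxels are
treated as the full reference population. Both conventions are fixed choices;
the quantitative framework they serve states neither.

Annotation of a study proceeds as:

1. body contour at 0.1 SUL (largest 6-connected component, holes filled);
2. automatic liver VOI placement (below);
3. candidate segmentation: all 6-connected clusters of at least 7 voxels at
   or above $T_b$, classified externally (component id to class-name table,
   standing in for expert review);
4. label-map assembly: `Background` outside the contour, `Nominal` inside,
   the VOI as `Reference`, candidates as assigned — a complete partition;
5. Round-Robin growth of the Reference at $T_r$, re-measurement of
   $\mu_L, \sigma_L$ over the grown region, and a fresh threshold set;
6. Round-Robin growth of all organ/lesion classes at the new, slightly lower
   $T_f$, letting avidity-based segmentations fill out their anatomy.

### Round-Robin region growing

The growth scheme is deliberately self-limiting. The eligible pool starts as
all `Nominal` voxels at or above the growth threshold. Each cycle (a) annexes
every pool voxel face-adjacent to a growing region, then (b) erodes the pool
by one voxel (its 6-connectivity boundary layer). Because the pool strictly
shrinks, growth terminates on its own, and regions cannot creep arbitrarily
far beyond their anatomic boundary. Two details are fixed here because the
verbal description leaves them open: "shrunk by 1 voxel" is implemented as
morphological erosion of the pool (the alternative — removing exactly the
annexed layer — is noted but not used), and when two classes reach the same
voxel in one cycle, the class whose frontier voxel has the higher PET value
wins, with ties going to the lower vocabulary index. Both choices are
deterministic and are validated in the test suite against an independent
literal step simulator on random grids.

### Liver VOI placement

The automatic search scans candidate centres on a coarse grid (stride 2
voxels). A candidate must (i) fit a 3 cm^3 sphere (radius 8.947 mm) entirely
inside the body and (ii) have a sphere mean SUL in a plausible hepatic band
(1.0–3.0). Among the survivors, the centre minimising the coefficient of
variation of a **margin-enlarged** sphere (radius + 7 mm, two PET voxels)
wins. Scoring homogeneity over the enlarged support is the package's own
refinement: a bare minimum-CV rule can be captured by small homogeneous
structures of liver-like intensity (renal cortex, blood pool), whereas only a
large homogeneous organ also looks homogeneous on the enlarged sphere —
boundary dilution penalises everything else. A user-supplied centre bypasses
the search entirely (the manual escape hatch every clinical tool needs).

## Preprocessing and training data

Studies are resampled to 3.5 mm isotropic voxels (trilinear for PET/CT,
nearest-neighbour for labels), centre-cropped in-plane (128 x 128 by
default), and the PET is smoothed with a 1 cm^3 spherical mean filter
(radius 6.203 mm). The order — resample, crop, then smooth — follows the
workflow's data-cleaning stage; a `smooth_first` flag exists for sensitivity
testing. Near the grid edge the smoothing kernel is renormalised over its
in-bounds voxels so constants are preserved exactly.

Slices are exported integer-encoded: PET as round(SUL x 100) (3.27 SUL is
stored as 327), CT as HU + 1024 clipped at zero (the offset makes the encoding
invertible while keeping air at 0). Each slice becomes one little-endian
binary file (int32 header `{magic, rows, cols, channels}`, int16
channel-major payload) plus an 8-bit PNG whose pixel value is the vocabulary
index; all files of a slice share a basename. Class weights for the loss are
reciprocal class frequencies over the training voxels, normalised so present
classes have mean weight 1; absent classes get weight 0 so they cannot
dominate the loss.

## The network

The classifier is a 2D U-Net over 128 x 128 two-channel slices: four
down-sampling stages of double 3 x 3 convolutions (each followed by batch
normalisation and ReLU), feature width doubling from 128 to a 2048-channel
bottleneck at 8 x 8, a mirrored decoder with nearest-neighbour upsampling,
halving convolutions and concatenation skips, and a head of 1 x 1
convolution to 16 features, batch normalisation and softmax. (The published
bottleneck shape "8 x 8 x 2 x 2048" carries an extra "2" whose meaning the
text does not explain; the descriptor records spatial 8 x 8 with 2048
channels and a note.) Skip connections use plain concatenation with standard
double-conv blocks; the compound "multi-resolution" blocks of the cited
architecture figure are schematic and are not reproduced.

The implementation is native vectorised R: convolutions are shifted-gather
("im2col") matrices multiplied by offset-blocked weight matrices through
BLAS, with hand-derived backward passes for every layer (convolution, batch
norm, ReLU, max-pool, upsample, weighted softmax cross-entropy). The entire
backward pass is verified against central finite differences in the test
suite (relative error below 1e-4 at probe parameters across all layer types).
Training is plain SGD with momentum; per-epoch training and validation losses
are logged and the best-validation checkpoint is retained. Default solver
settings (learning rate 0.01, momentum 0.9, batch 16) are conventional SGDM
values; all are configurable and recorded in the returned history.

The loss is a class-weighted cross-entropy with weighted-mean reduction,
$L = \sum_p w_{c(p)} (-\log q_{c(p)}(p)) / \sum_p w_{c(p)}$, so uniform
weights reduce to the ordinary mean and the magnitude is invariant to weight
rescaling.

Augmentation draws, independently per image per epoch, an in-plane
translation (±5 px), rotation (±10°) and scale (50–200%), applied identically
to both channels and the labels with nearest-neighbour resampling (labels
never acquire new values; channels stay integer). Augmentation can be
disabled, and is disabled in the phantom-scale training exercise: phantoms
are geometrically standardised by construction, and a fixed pipeline keeps
the exercise deterministic given its seed.

### Study-level folds

Cross-validation is study-level: studies are shuffled and split into 2K
groups; fold *i* takes group *i* as test, group *K + i* as validation and
the remaining 2K − 2 groups as training. With 130 studies and K = 5 this is
104/13/13 per fold, no study appears in two partitions of a fold, and no
study is tested in more than one fold (65 test slots in total — half the
cohort, matching the published design; a K-fold rotation in which every study
is tested once cannot produce 104/13/13 partitions of 130).

## Post-processing

Raw slice predictions are restacked into 3D. The predicted `Reference`
voxels are projected onto the PET volume, $\mu_L, \sigma_L$ re-measured, and
the follow-up threshold applied: every voxel of every tissue class (all
classes except `Background`, `Nominal`, `Reference`) with PET below $T_f$ is
reassigned to `Nominal`. Reference is exempt — it is a reference, not a
finding. The operation is idempotent. Whether a tissue component shrunk below
7 voxels should be dropped is not specified anywhere; components are kept by
default, and `min_component_size = 7` re-applies the candidate rule (the
end-to-end phantom exercise uses 7, mirroring the annotation-side minimum).
VOIs are then extracted per connected component per class with volume (mL),
SUL-Max, SUL-Mean and SUL-Peak (1 cm^3 sphere at the hottest voxel).

## Evaluation

Voxel level: 16 x 16 confusion matrices (rows truth, columns prediction),
optionally with `Primary_Lesion` and `Lymphadenopathy` pooled into a single
`Disease` class; one-vs-rest sensitivity, specificity, Dice and Jaccard per
class, with empty-denominator metrics reported as `NA` (not applicable),
never as 0.

Study level: Disease masks are the union of the two lesion classes in truth
and prediction; 3D Dice/Jaccard on the masks and the percent difference in
SUL-Max, $100 (S_{pred} - S_{truth}) / S_{truth}$ (sign convention: positive
means the prediction is hotter). Concordant-negative studies (both masks
empty) are non-scorable. Discordant studies (exactly one empty) score 0 for
Dice/Jaccard but have no calculable SUL-Max difference. Aggregation offers
the two published conventions: CLEANED drops every study with any
incalculable metric (only studies where both masks contain Disease remain);
CORRECTED keeps all studies, substituting the perfect value for each
incalculable metric (1.0 for Dice/Jaccard, 0% for the SUL-Max difference).

## The phantom generator

The generator emulates exactly the statistical structure the workflow
assumes, with analytic ground truth:

| region | geometry | mean SUL | SD | HU |
|---|---|---|---|---|
| air background | — | ~0 | 0.005 | −1000 |
| body (soft tissue) | ellipsoid 95 x 85 x 80 mm | 0.7 | 0.15 | 40 |
| liver | ellipsoid 36 x 30 x 26 mm | 2.2 | 0.25 | 55 |
| heart | ellipsoid r ≈ 22 mm | 4.0 | 0.3 | 45 |
| bladder | sphere r = 16 mm | 9.0 | 0.5 | 10 |
| kidneys (2) | ellipsoids 14 x 11 x 16 mm | 3.0 | 0.3 | 35 |
| primary lesion | sphere r = 11 mm | 6.0 | 0.4 | 50 |
| lymph node | sphere r = 9 mm | 5.0 | 0.35 | 50 |

The default grid is 64 x 64 x 48 at 3.5 mm isotropic (224 x 224 x 168 mm).
Uptake levels are typical clinical FDG SUL magnitudes; with the liver at
2.2 ± 0.25 the baseline threshold is 3.8 SUL, so the planted lesions clear it
by more than 3 liver SDs while the kidneys sit deliberately *below* it — a
realistic confounder: kidney-intensity tissue is never annotated as a
candidate, so the network must learn to distinguish it from lesion rims of
similar smoothed intensity by context. The lesion sizes (r = 9–11 mm) are
ordinary breast-lesion scales, two to three voxel radii at PET resolution.

PET noise is independent Gaussian per voxel around each region's mean,
clipped at 0, with no point-spread blur — ground truth stays exact, and the
1 cm^3 smoothing step emulates resolution effects where the workflow expects
them. CT is piecewise-constant HU plus Gaussian noise; it is an auxiliary
channel, so contrast (not realism) is the goal. Geometries are ellipsoids,
spheres and boxes with exact analytic membership; overlapping regions are an
error rather than a silently resolved ambiguity.

What phantoms do **not** emulate: scanner point-spread and partial-volume
effects at lesion rims, reconstruction artefacts, respiratory motion,
heterogeneous tracer uptake within organs, anatomic variability of organ
shape and position, and attenuation-correction interplay between the CT and
PET channels. Passing phantom tests therefore demonstrates the correctness
and internal consistency of the workflow's machinery — thresholds, growth,
geometry, learning dynamics, post-processing algebra — not clinical-grade
detection performance on real patients.

## Scaled-down learning exercise

The test suite trains a reduced network — initial features 8, depth 3, 64 x
64 slices (the phantom torso fits a 64-voxel crop at 3.5 mm) — on ten
phantoms (eight training, two validation studies; every other slice, about
190 training slices), 30 epochs of SGDM at learning rate 0.01, momentum 0.9,
batch 8, class weights from the training labels, seed fixed. Five held-out
phantoms (three with lesions, two without) are annotated, predicted,
post-processed with the follow-up threshold and the 7-voxel rule, and scored
at study level. The problem sizes keep the exercise reproducible on a single
CPU; they are stated here so the conditions of the exercise are explicit.

## Numerical choices and degenerate inputs

* Voxel indexing is 1-based `(row, column, slice)` in column-major R arrays;
  the physical centre of voxel `[1,1,1]` is the volume origin. Crops use
  closed index ranges; odd crop/pad remainders go to the high-index side.
* Rounding of PET encoding is half-away-from-zero (values are non-negative,
  so `floor(x + 0.5)`), fixed for cross-platform determinism.
* Resampling clamps sample coordinates to the source grid (border
  replication); a volume already at target spacing is returned untouched,
  bit for bit.
* Population SD everywhere a reference SD is measured; `liver_stats`
  requires a positive mean.
* Batch-norm uses batch statistics in training and running averages
  (momentum 0.1) at inference; the variance floor is 1e-5. Posteriors are
  clamped at 1e-12 inside the loss.
* Empty candidate lists, empty VOI tables and all-`Nominal` predictions are
  legal values, not errors; a prediction without `Reference` voxels is an
  error because the post-processing threshold is then undefined.
* Ties in max-pooling argmax and in per-pixel argmax resolve to the first
  (lowest) index deterministically.

## Known limitations

* The native R network is CPU-bound and desk-scale: the full 128-feature,
  depth-4 configuration (~10^8 parameters) is described by the descriptor
  and buildable, but training it is far outside a test budget; correctness
  at scale is argued by the architecture arithmetic plus gradient checks at
  small scale, not by a full-scale training run.
* Only the baseline (single time point) side of PERCIST is implemented;
  response classification across time points is out of scope.
* DICOM I/O is replaced by a documented per-slice NIfTI + JSON container
  (no DICOM stack is available to R here); the geometry and metadata
  semantics mirror what a DICOM PET series carries.
* The liver search assumes hepatic parenchyma is the largest homogeneous
  structure in its intensity band; grossly infiltrated livers would defeat
  it — exactly the situation in which PERCIST itself prescribes a different
  reference region, and where the manual centre override applies.
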