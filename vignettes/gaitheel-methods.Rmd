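---
title: "Marker-less heel keypoint detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-less heel keypoint detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical mobility tests such as the Timed Up and Go (TUG: rise from a
chair, walk 3 m, turn, walk back, sit down) are usually scored with a
stopwatch. Video recordings of the same test carry far richer information —
step length and step width in particular — but extracting them without
markers requires locating the point where the heel contacts the floor with
sub-centimeter accuracy. General-purpose pose estimators output a heel
keypoint among their 25 body keypoints, but not at the accuracy clinical
use demands.

`gaitheel` implements a two-step refinement pipeline:

1. **Coarse stage.** Whole-body pose trajectories (BODY_25-dialect JSON,
   25 keypoints per frame at 25 Hz) are used to find the stretches of video
   that contain gait, to approximate each heel-strike event by a peak in
   the heel-to-heel image distance, and to crop a fixed 160 x 120 px window
   around the foot (centered on the mean of the ankle, big-toe and heel
   keypoints).
2. **Fine stage.** A convolutional network trained specifically for this
   task predicts the heel contact point inside the crop: the most posterior
   point of the heel touching the floor in side views, the most lateral
   such point in frontal views.

A planar homography estimated from marked floor points maps image
predictions to floor coordinates (cm), where step length (along the
walking x axis) and step width (along the lateral y axis) are differences
between successive alternating-foot heel contacts, and where prediction
errors are measured along the single floor axis that matters for each
view.

## Floor calibration

Five to eight floor points with known world coordinates are marked in each
camera view. `estimate_homography()` uses the normalized direct linear
transform: Hartley normalization of both point sets (centroid to origin,
mean distance sqrt(2)), SVD null vector of the 2n x 9 design matrix,
denormalization, and scaling to `h[3,3] = 1`. No nonlinear refinement is
applied; for noiseless consistent input the estimate is exact to machine
precision, which the tests verify by round-tripping scenes from the
synthetic generator. Degenerate configurations (collinear points) are
detected through the second-smallest singular value and rejected.

## Event detection

The heel-strike frame is approximated by a local maximum of the absolute
heel-to-heel distance: at the moment the leading foot lands, the two heels
are maximally separated. The distance series (with undetected frames
filled by linear interpolation) is smoothed with a 3-frame moving average;
interior local maxima with topographic prominence of at least 5 px are
kept, and peaks closer than 10 frames (0.4 s at 25 Hz, below any plausible
step time) are pruned keeping the higher peak, earlier on ties. All three
parameters are configurable; the source protocol corrected peaks by visual
inspection, so no published values exist for them and the defaults were
fixed a priori from gait timing.

Gait intervals — separating walking from sitting, standing and turning —
are taken as stretches where the smoothed forward heel speed stays above a
threshold (default 30 px/s) for at least 0.5 s.

## Dataset and augmentation

Labelled samples pair a 160 x 120 crop with its heel point in crop
coordinates. Augmentation applies 20 random translations of the *crop
window* (each axis independently uniform on the integers -30..30, i.e. a
uniform distribution of width 60 px), re-cropping from the source frame so
no synthetic padding enters the data, and horizontally flips each
translated crop; originals are not re-included, so each sample yields 40.
This x40 factor reproduces the corpus arithmetic of the study the package
models: 4,824 side-view originals give 192,960 (~193 k) training images and
2,756 frontal originals give 110,240 (~110 k).

Two readings of "width 60" are possible (offsets in [-30, 30] or in
[0, 60]); the symmetric one is used, as the natural reading for an
augmentation centered on the original. Flips are horizontal only, since
left and right feet mirror each other.

Splits are by *subject*, never by image: subjects are shuffled with a
fixed seed and partitioned (the modelled study used 157 / 9 / 18 of 184),
and every original and augmented sample of a subject lands in exactly one
split, so no subject appears on both sides of an evaluation.

## Keypoint networks

Six variants combine three standard ImageNet backbones — VGG19,
ResNeXt50-32x4d, MobileNetV2 — with two heads:

* **Regression head**: the full backbone including its 1000-way output,
  followed by a fully connected 1000 -> 2 layer. A sigmoid keeps the output
  in [0, 1]^2; it is interpreted as the heel position normalized to the
  crop size, (x/160, y/120).
* **Heatmap head**: the backbone's feature-extraction layers only (for
  VGG19 the 16 convolutional layers; for MobileNetV2 and ResNeXt50
  everything except the classifier), followed by five transposed
  convolutions (kernel 4, stride 2, padding 1, each with batch
  normalization and ReLU) and a final 1x1 convolution to one channel. Five
  doublings take the stride-32 feature map back to roughly input
  resolution; the exact output size depends on the backbone (160 x 128 for
  MobileNetV2, 160 x 96 for VGG19 at 160 x 120 input), and the decoder
  records grid-to-input scale factors. Whenever the response grid covers
  the crop (MobileNetV2's 128 rows over 120), the grid-to-crop mapping is
  the identity rather than a linear rescaling: a convolutional decoder is
  translation-equivariant, so it can realize the constant alignment shift
  an identity mapping needs, but not the position-dependent offset a
  rescaled target grid would demand — with the scaled mapping the trained
  models showed a systematic axis bias that the identity mapping removes.
  Only when the grid is smaller than the crop (VGG19's 96 rows) is linear
  scaling used, since identity could not address the full crop.

The engine behind these models is a compact CNN implementation written for
this package (im2col/GEMM convolutions, transposed convolutions, batch
normalization, SGD with momentum in Rcpp/Armadillo), since no deep
learning framework is available to R here. The architectures follow the
published layer schedules exactly: the regression variants count
143,669,242 (VGG19) and 3,506,874 (MobileNetV2) trainable parameters —
143.7 M and 3.5 M, matching the published table once the 2,002-parameter
head is added to the standard backbone counts. The transposed-convolution
channel schedule of the heatmap head (default 256, 128, 64, 32, 16) is a
package choice — only the layer count and single-channel output are fixed
by the source — so heatmap-variant parameter counts are schedule-dependent
and are not treated as reproducible targets. The published ResNeXt50
regression count (29.0 M) also cannot be derived from the standard
ResNeXt50-32x4d definition (25.0 M including the head); the package builds
the standard architecture.

### Heatmap targets and decoding

Training targets for the heatmap head are isotropic Gaussians with peak 1
at the labelled heel, `exp(-((x-hx)^2 + (y-hy)^2) / (2 sigma^2))`; the
functional form is a package choice (the source shows target heatmaps but
never specifies them), with sigma = 3 px as the default. Decoding finds
the global maximum (ties broken toward the smallest row-major index) and
returns the intensity-weighted mean position over the 13 x 13 window
centered on it, with negative responses clamped to zero and the window
clipped at borders. The weighted (not unweighted) mean is used because an
unweighted mean of a fixed window would return the window center and carry
no sub-pixel information. Render-then-decode is an identity to better
than 0.1 px for keypoints at least 7 px from every border, and decoding is
exactly flip-equivariant.

## Training protocol

SGD with momentum 0.9 and weight decay 1e-4; mean-square error on the
prediction (normalized coordinates for the regression head, per-pixel on
the response map for the heatmap head); batch size in 8..12 and initial
learning rate in 1e-3..1e-2 tuned on validation data; learning rate
multiplied by 0.1 after 10 epochs; at most 20 epochs with early stopping
of patience 4 ("did not decrease" is read strictly: an epoch counts
against patience unless its validation loss is lower than the best seen).
The weights of the best-validation epoch are restored on stop, since that
is the model one would evaluate. Training is bit-reproducible under a
fixed seed: initialization, shuffling and dropout all flow from one RNG
stream, and the compiled kernels are deterministic. Models are always
trained per view; the trainer refuses mixed side/frontal sets.

## Synthetic data: what it emulates, and what it does not

The clinical recordings behind the modelled study are not public, so the
package generates all of its inputs:

* **Foot scenes** — a superellipse "dome" silhouette whose floor-contact
  span starts exactly at the requested heel position, plus a leg band,
  over smoothly textured background and floor, with randomized shape,
  texture and intensity. The geometric ground truth is exact by
  construction and is verified by scanning rendered masks. Scenes are
  rendered in a 320 x 240 virtual frame with the crop window at least
  30 px from every edge, so the +-30 px augmentation never needs padding.
* **Gait scenarios** — heel trajectories alternating stance plateaus and
  monotone smoothstep swings; the foot that lands at strike k stays
  planted until the other foot lands, then swings to its next contact.
  This guarantees the heel-to-heel distance has a local maximum exactly at
  every planted strike frame (for zero noise, under a similarity
  image-floor map). Strike world positions step by the configured step
  length and width, so the full event -> projection -> step-parameter chain
  has known answers.
* **Calibration scenes** — floor points on a jittered non-collinear grid
  projected through a known homography, with optional image noise.

What passing tests on these fixtures show is that the *pipeline machinery*
is correct: geometry, event logic, augmentation arithmetic, optimization,
decoding. What they cannot show is performance on real video — blur,
occlusion, clothing, lighting, pose-estimator failure modes and true
inter-subject variation are absent, so the published clinical error
magnitudes (median 0.55 cm for the best side-view model) are out of reach
by design and are not asserted anywhere.

## The desk-scale experiment

`desk_scale_experiment()` is the package's end-to-end check that a heatmap
model trained from random initialization learns heel localization. Problem
sizes are chosen for a single CPU with the compiled-R engine: 1,000
synthetic crops of distinct rendered scenes (800 train / 100 validation /
100 test, split by subject), a MobileNetV2 backbone at width multiplier
0.25 (the published MobileNetV2 family parameter) with a narrow
transposed-conv head (32, 16, 8, 8, 4), batch 8, and at most 12 epochs
under the standard schedule (decay by 0.1 after epoch 10, patience 4).

Three choices depart from the defaults used for fine-tuning, all because
this run trains from random initialization on a short budget, and all
tuned on validation data (the protocol's own tuning rule):

* **Gaussian target sigma = 16** instead of 3. With sigma = 3 the positive
  target mass is ~0.3% of the response map and plain SGD collapses to the
  all-zero heatmap; broad targets give the MSE loss usable gradients from
  the first epochs. Decoding accuracy is unaffected for interior keypoints
  (the 13 x 13 weighted mean of a symmetric peak is exact).
* **Learning rate 0.25** above the 1e-3..1e-2 band used when fine-tuning
  pretrained backbones; from-scratch training of a batch-normalized network
  tolerates and needs the larger steps on this step budget.
* **Zero-initialized final response layer** (part of [build_model()] for
  every heatmap head): the response map starts at zero, so early training
  shapes it instead of first shrinking a random one.

The acceptance check asserts a held-out median keypoint error of at most
3 px. Under a nominal side-view calibration of 0.25 cm/px the same errors
are also summarized in centimeters, to exercise the floor-axis error path;
no clinical claim attaches to that number.

## Numerical choices and degenerate inputs

* Quartiles use linear interpolation of the order statistics (rank
  `k/4 * (n-1)`, 0-based — R's default type 7), matching the box-plot
  convention of the summarized figure family; outliers lie beyond 1.5 IQR
  from the quartiles and whiskers end at the most extreme non-outliers.
* Crop windows near frame edges are shifted, not padded, to preserve real
  pixels; the recorded origin keeps crop-to-frame mapping exact.
* Multi-person pose frames take person 0; frames with no person yield
  all-zero-confidence frames rather than errors.
* Homography projections reject points whose homogeneous component falls
  below 1e-12 ("point at infinity").
* All-zero (after clamping) heatmaps are reported as undecodable rather
  than silently returning a corner.
* The 4x image upscaling used in the original labelling workflow is a UI
  aid only and has no computational counterpart here.

## Known limitations

* The CNN engine is CPU-only, double precision, and sized for desk-scale
  studies; training the full-width networks on a 193 k-image corpus is out
  of its intended scope.
* Pretrained ImageNet backbone weights are supported as an initialization
  hook but not shipped; all packaged experiments train from scratch, which
  is the main reason the desk-scale task uses simplified synthetic scenes.
* Heel-strike detection assumes roughly straight walking past the camera;
  turns are expected to be excluded by the gait-interval step first.
* Toe-off events, gait-phase durations and joint angles are out of scope.
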