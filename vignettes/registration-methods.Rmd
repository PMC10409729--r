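---
title: "Slice-to-volume rigid registration of CT to breathing ultrasound: models and methods"
author: "SliceVolReg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-to-volume rigid registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Percutaneous kidney interventions are guided by 2D ultrasound while the
diagnostic anatomy lives in a 3D CT volume. Aligning the two means
finding, for every ultrasound frame of a free-breathing sequence, the
rigid pose of the CT volume whose central sagittal slice shows the same
cut through the kidney as the frame. This is *sliced* 3D–2D
registration: no projective geometry is involved, and because the
kidney barely deforms under breathing, a 6-parameter rigid transform
per frame (3 rotations, 3 translations) is an adequate motion model.

Two difficulties shape the design. First, the dimension gap: a single
2D frame constrains a 3D pose only weakly, so frames are processed in
overlapping time windows of `Nw = 5` consecutive frames, embedded as a
thin slab in a zero-padded 3D volume along the RL axis, with the middle
frame as the registration target and the neighbours contributing motion
regularisation. Second, the modality gap: CT and ultrasound intensities
are unrelated, so alignment is measured on (a) per-voxel kidney
probability maps produced by feature networks and (b) the
modality-independent neighbourhood descriptor (MIND), which encodes
local self-similarity instead of raw intensity.

`SliceVolReg` implements the whole two-step pipeline: feature U-Nets,
the hierarchical registration network trained unsupervised under the
feature–image–motion (FIM) loss, training-data generation from
truncated-Gaussian transform sampling, one-cycle transfer learning, and
contour-distance evaluation — plus a synthetic-phantom module standing in
for clinical data, which cannot be distributed.

## Coordinate and transform conventions

Volumes are stored in RAI axis order (RL, AP, IS) with voxel centres at
`origin + index * spacing` (0-based indices). A `RigidTransform` acts
on world coordinates as `T(x) = R (x - c) + c + t`, rotating about the
centre `c` (by default the grid centre of the volume at hand). The
rotation is composed from intrinsic elementary rotations in axis order
RL, AP, IS: `R = R_RL(a1) R_AP(a2) R_IS(a3)`. No convention for the
Euler order, the rotation centre, or the unit mixing in the transform
loss is inherited from elsewhere; all three are free design choices
here, made once and used consistently by training and evaluation, and
all are configurable.

`resampleRigid()` applies a transform to image content: the output at
`x` samples the input at `T^{-1}(x)`, trilinearly (or nearest
neighbour), with samples outside the volume set to zero — zero is the
natural background because the ultrasound window volume is itself
zero-padded. The resampler is differentiable with respect to the six
pose parameters; this is the spatial-transformer contract that lets the
registration loss backpropagate into the network.

In the 4x4 matrix view used by the transform loss, the translation
column is divided by a reference length (default: one voxel) so that
rotation entries (dimensionless) and translation entries become
commensurate in the Frobenius norm.

## The synthetic phantom

No clinical CT/US pairs are distributable, so the package generates its
own study material. A phantom is an ellipsoidal "kidney" (default
semi-axes 25 x 30 x 55 mm, the scale of an adult kidney) of intensity 1
over a darker background (0.25), with a smooth random internal texture
field (amplitude 0.3) and, optionally, a hypoechoic off-centre blob
emulating internal renal structure such as the pelvis or a lesion. The
mask is the exact analytic ellipsoid. The ultrasound sequence is the
central sagittal slice of the phantom under a sinusoidal breathing pose
(dominant IS translation, small rotations — the two motion components
visible in real sequences), remapped through a gamma curve so CT and US
intensities are *not* linearly related, blurred, and corrupted with
multiplicative log-normal speckle. Mask frames are sliced from the
warped exact mask without noise, and the exact per-frame poses are
recorded.

What the phantom deliberately does not model: acoustic shadowing and
rib occlusion, scan-conversion geometry, organ deformation, and the
shape complexity of a real kidney (it is a textured ellipsoid). Tests
passing on phantoms therefore demonstrate the correctness of the
machinery and the behaviour of the method under known ground truth, not
clinical-grade accuracy.

## The FIM loss

Given fixed window volume `I_fix`, moving CT `I_mov`, feature maps
`M_fix`, `M_mov` and the window's transforms `D`, the training
objective is

```
L = L_f + lambda1 * L_i + lambda2 * L_d,   lambda1 = 0.01, lambda2 = 0.001
```

* **Feature term** `L_f`: for each frame `i`, the CT feature map is
  warped by `D_i`, its middle RL slice is taken, and the *elementwise*
  Dice `mean(2xy / (x + y + eps))` against frame i's feature map is
  computed; the term is the negative mean over the window. The
  elementwise formula (with `eps = 1e-6` guarding 0/0 at background
  pixels) is used only here; segmentation quality elsewhere uses the
  set Dice. For binary maps the elementwise Dice equals the fraction of
  agreeing foreground pixels, so even a perfectly aligned pair scores
  the foreground fraction, not 1 — the *optimum location*, not the
  value, is what drives registration.
* **Image term** `L_i`: the CT is masked by elementwise multiplication
  with its feature map, warped by the middle frame's transform, and
  compared to the fixed window volume through the mean absolute MIND
  channel difference on the middle RL slice. The mean runs over both
  the six displacement channels and the slice pixels.
* **Motion term** `L_d`: `0.01 * mean ||D_i - I||_F / refLength-normalised
  + 0.99 * gradD`, where `gradD` is the mean Frobenius norm of the
  second difference `D_{i+1} + D_{i-1} - 2 D_i` over interior frames.
  Constant-velocity motion across the window is annihilated by the
  second difference; the small magnitude term keeps poses near the
  pre-aligned start.

### MIND construction

For each voxel and each of the six face-neighbour displacements, the
patch distance is the 3x3x3 mean of squared intensity differences
between the patch at the voxel and the displaced patch, computed on a
zero-padded copy of the volume. The variance estimate `V(x)` is the
mean of the six distances, floored at `1e-6 * dynamicRange^2`; channels
are `exp(-D_p / V)` divided by the per-voxel maximum, so the strongest
channel is exactly 1 and all channels lie in (0, 1]. On a constant
image every interior channel is 1 (boundary voxels see the zero
padding). Because `V` normalises per voxel, the descriptor — and hence
the image loss — is insensitive to affine intensity remapping, which is
what makes a CT-to-ultrasound comparison meaningful.

Numerical details: the Frobenius norms in the motion term evaluate
exactly but use a floored denominator in their gradient so that
training can start from the exact identity (where the norm is zero and
the true derivative is undefined).

## Feature networks

Each modality has a 5-level residual U-Net. Residual blocks are
(conv – instance norm – ReLU) x 2 with an additive identity skip,
projected by a 1x1x1 convolution when channel counts differ; encoder
levels downsample with stride-2 convolutions (never along the 5-frame
time axis of the ultrasound configuration); decoding upsamples with
nearest neighbour. Skip connections pass through a local binary
convolution (LBC) layer: a fixed bank of sparse ternary {-1, 0, +1}
3x3x3 filters (nonzero with probability 0.5, seeded and serialised with
the model) applied to the channel mean, a ReLU, and a bias-free
trainable 1x1x1 combination added residually to the skip tensor. The
fixed filters inject handcrafted texture features and are never
trained. Dropout (rate 0.2) sits at the bottleneck and after each
decoder block. The output layer is a 1x1x1 convolution with sigmoid
activation, yielding a per-voxel kidney probability.

Training minimises the negative set soft-Dice with Adam at learning
rate 1e-4, batch size 1. Whole-volume prediction tiles the volume with
50% overlapping patches blended by separable triangular weights (a
blend that preserves constants). The full-scale configurations use
encoder filters 16–256 with 160x160x80 CT patches and 256x192x5
ultrasound windows; the desk configuration used by the tests scales the
filters to 4–64 and the patch to 32x48x64.

## Registration network

The concatenated (CT feature, US feature) pair passes through three
stride-2 encoder convolutions (8, 16, 16 filters) and six decoder
convolutions (16, 16, 16, 16, 8, 8) with encoder skip concatenation and
nearest-neighbour upsampling. The printed decoder has six entries but
only four translation weights, so four scales emit transforms; the
assignment here is two convolutions at 1/8, two at 1/4, one at 1/2, and
one at full resolution, with a transform head after the last
convolution of each scale. Each head is global-average-pooling followed
by a dense layer with tanh activation emitting `6 Nw` parameters
(a flatten-then-dense head is available as a configuration option; it
has a vastly larger parameter count and is memory-hostile, so pooling
is the default).

tanh outputs are scaled to ±30 degrees for rotations and ±16 voxels *of
the emitting scale* for translations (±4 on the quarter-scale desk
grid — the range scales with the grid). The final dense layers are
zero-initialised so the untrained network predicts the identity warp
exactly, which unsupervised training needs for a stable start.

Per-scale predictions combine hierarchically: rotation is scale
invariant and is averaged; translation is inversely proportional to
resolution and is combined with weights (2, 1, 0.5, 0.25) from the 1/8
scale to full resolution, yielding full-resolution voxel displacements
converted to mm through the spacing. A unit translation predicted only
at the 1/8 scale therefore moves the volume by exactly two
full-resolution voxels.

## Training strategy

**Pre-alignment.** The CT kidney centroid is translated onto the US
window's feature centroid before the network sees the pair (the IS
alignment and the centroid matching are one explicit translation here;
both in-plane crops centre on the kidney feature centroid, mirroring
the CT crop, since no other anchor is specified anywhere).

**Training-pair generation.** The six rigid parameters of the
transforms that map pre-aligned CTs onto their verified reference
alignments are modelled parameter-by-parameter as Gaussians, truncated
at two sigma by rejection sampling (rejection preserves the Gaussian
shape inside the band, clipping would not). Sampling `Nt` transforms
and applying their inverses to a reference-aligned CT produces `Nt`
training pairs whose ground truth is known by construction but is never
used in the loss — it is a diagnostic only, and the tests verify that
deleting it changes nothing. A group of small misalignments is
parameterised by its mean L2 magnitudes (rotation 10.37 degrees,
translation 3.69 mm); per-axis widths follow from the chi distribution
with three degrees of freedom, `sigma = L2mean / (2 sqrt(2/pi))`.

**Pretraining and one-cycle transfer.** One registration model is
pretrained unsupervised over pairs pooled from all patients, then
refined per patient on the windows of the first respiration cycle for
exactly two epochs, all weights trainable, returning a copy and leaving
the pretrained model untouched. The first cycle is detected as the
frames up to the second zero-crossing of the mean-centred IS centroid
trajectory of the US feature maps (an explicit override exists).
Pretraining holds out 10% of pairs for early stopping (patience on the
validation loss); the best-validation parameters are kept.

### Desk-scale schedule

The desk benchmark runs 20 synthetic patients on 32x56x72 grids at
3.2 mm spacing (the full profile divided by four; the two profiles
share every code path). Sequences have 20 frames with a 12-frame
breathing period — a quarter-scale cycle, keeping the first-cycle
window count and hence the whole run within a desktop CPU budget; each
patient contributes 2 generated training pairs and pretraining runs 4
epochs. A full-scale training performs hundreds of thousands of
optimiser steps at learning rate 3e-4; the desk schedule has a few
hundred steps in total, so its Adam step sizes are scaled up
correspondingly (0.01 for shared pretraining, 0.05 for the per-patient
transfer, whose two epochs must converge within roughly twenty steps).
The model configuration keeps the full-scale default (3e-4). The
feature-network overfit check disables dropout and uses 3e-3 for the
same reason: it is a memorisation check, and regularisation only slows
the memorisation.

## Evaluation

Kidney outlines are extracted from thresholded (0.5) mask slices as
foreground pixels with at least one background 4-neighbour. The
Hausdorff distance (symmetric max–min) and the mean contour distance
(symmetric mean, pooled over both contours) are computed by sampling
each contour's Euclidean distance transform at the other contour's
points; the all-pairs computation is kept as the test oracle. CT–US
distances compare the estimated CT plane against the ultrasound frame
mask; CT–CT distances compare the estimated plane against the plane
under the ground-truth pose. Pose errors are the L2 norms of the
component-wise rotation (degrees) and translation (mm) differences.
Reports give mean ± sd per sequence, matching the usual reporting
shape. On synthetic out-of-plane errors the 2D CT–US distance
under-reports the 3D error, since the out-of-plane component is
invisible in the slice — the tests check this direction explicitly.

## Known limitations

* **Long-axis rotation is weakly identified.** For a near-ellipsoidal
  kidney, rotating about its IS (long) axis barely changes the central
  sagittal section of the feature mask, so only the weakly weighted
  MIND term (lambda1 = 0.01) carries that component's sign and
  magnitude. Its gradient is roughly two orders of magnitude smaller
  than for the in-plane components; within a two-epoch transfer budget
  the IS component is corrected only partially, and parameter-recovery
  statistics on the desk benchmark are dominated by this axis. The
  contour distances — the clinically meaningful quantity — are almost
  unaffected, for the same geometric reason.
* The desk phantom's texture is smoother than real speckle statistics,
  and the feature maps used in the registration benchmark are exact
  masks rather than network outputs, isolating registration behaviour
  from segmentation error.
* The elementwise Dice saturates at the foreground fraction, so
  absolute loss values are not comparable across phantoms with
  different kidney sizes; only differences matter.
* Batch size is fixed at 1 and instance normalisation is used
  accordingly; no multi-sample batching is implemented.

## Reproducing the numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` runs the
desk benchmark and the feature-network overfit from scratch and writes
the summary quantities as JSON. The test suite
(`tests/testthat/test-acceptance.R`) re-derives the numerical
primitives against independent brute-force oracles and runs the same
benchmark with fixed seeds.
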