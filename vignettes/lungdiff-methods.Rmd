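---
title: "Comparing chest radiographs over time: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing chest radiographs over time: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungdiff)
```

## The problem

Thoracic physicians routinely compare a patient's current chest radiograph
with an earlier one to judge whether a finding is new, growing, or stable.
Doing this by eye is slow and error-prone: the two films differ in patient
pose, inspiration depth and detector calibration, so genuine change is
entangled with nuisance variation. `lungdiff` implements a four-stage
pipeline that removes as much nuisance variation as possible before
presenting the residual difference:

1. **Lung-field segmentation** restricts all further processing to the lung
   region, either with a classical image-processing chain or a small
   anchor-based detector network.
2. **Deformable registration** warps the earlier (*pre*, "working/moving")
   lung crop onto the later (*post*, "reference/fixed") crop, after
   histogram matching removes detector brightness differences.
3. **Difference mapping** computes `D = Img2 * |Img2 - Img1|` on the
   aligned unit-range crops and optionally amplifies subtle change with a
   sigmoid-style transform, rendering the result as a heat map.
4. **Classification** predicts a 12-way multi-hot disease label vector from
   the post image alone (single-input) or from the post image plus the
   difference image (dual-input).

Because paired clinical radiographs cannot ship with a package, a phantom
generator produces synthetic pre/post pairs with exact ground truth, and
every stage is tested against it.

## The phantom: a stated world

`phantom_spec()` renders a dark background, a bright thoracic ellipse, two
dark elliptical lung fields, periodic rib bands crossing the thorax, a
gastric air bubble under the left hemidiaphragm, and optional bright
lesions with a sharp core and a 1.5-px cosine edge taper (the taper sits
*outside* the mask radius, so the mean rendered delta over the lesion mask
equals the requested delta). A pair is produced by pulling the pre anatomy
back through a smooth random displacement field (control-grid spacing 64 px
at the 512 scale, maximum magnitude 6 px — below the spacing, so the warp
does not fold), adding any new lesions, applying a detector gain/offset
(`gain in [0.95, 1.05]`, `offset in [-0.03, 0.03]`), and adding Gaussian
noise (sigma 0.01 of the unit range). These defaults are fixed once as a
plausible between-visit variation regime and are not revisited per test.

Two design points deserve explanation:

* **The gastric air bubble.** The classical chain ends by deleting
  connected components smaller than the mean component area. On a phantom
  whose morphology step leaves exactly the two (nearly equal) lung
  components, that rule degenerates: the smaller lung falls a few pixels
  below the mean and is deleted. Real radiographs always contain mid-size
  dark structures (gastric bubble, trachea, markers) that anchor the mean
  below the lung areas; the bubble plays that role here. It is anatomy the
  rule was designed for, not a tuning knob.
* **Benign mimics (`distractor_list`).** Lesion-shaped blobs present at
  *both* time points, excluded from labels. They exist so one can build
  classification tasks where the post image alone is uninformative and
  only the temporal difference identifies the disease — the situation the
  dual-input architecture is meant to exploit.

What a green phantom test does **not** establish: anything about real
anatomy (no airway trees, no cardiac silhouette, no projection physics),
real label noise, or real inter-patient variability. Phantom results are
directional evidence that the implementations do what they claim, at a
scale where a CPU can train the networks in minutes.

## Classical segmentation

`segment_classical()` runs CLAHE (clip limit 2, 8x8 tiles — the method
names no parameters, these are common radiograph practice and are
config-exposed), Otsu binarization (threshold maximizing between-class
variance; pixels above the threshold become white), removal of components
touching the image border ("background-related"), morphological opening
then closing with a rounded discrete disk (radius 3 at the 512 scale;
radius 1 is the full 3x3 square so opening preserves rectangles), removal
of below-mean-area components, and a bounding box with a 10-px allowance at
the 512 scale, mapped back to the input resolution. Polarity is
auto-detected: the Otsu class whose mean matches the border ring is taken
as background-like, and the lungs are segmented from that (dark) class
after border-component removal. Erosion treats out-of-image as foreground
so masks are not eaten at the border.

## Registration

Both engines share one field convention: **pull-back sampling** — the
warped image samples the moving image at `p + field(p)` with bilinear
interpolation and replicate-edge borders. A zero field is the identity; a
constant integer field is an exact array shift.

**Classical.** Dense-field gradient ascent on a similarity metric; the
field is Gaussian-smoothed (sigma 2 px) after every update and the largest
per-iteration update is capped at 0.25 px. The metric is selected by
configuration — windowed (ANTs-style) neighborhood correlation with radius
4 by default, or joint-histogram mutual information — never a sum of the
two, since the source material does not state how they would combine. Both
metrics have analytic gradients: the local-correlation gradient is
assembled from box-filtered window statistics; the MI gradient uses
adjacent-bin differences of the log-ratio table (a partial-volume
approximation). A 2-level coarse-to-fine pass (quarter scale, then full
scale) is the default because a purely local ascent at full resolution
cannot recover multi-pixel translations across flat image regions.

**Learned.** A U-Net predicts the field in one pass: four stride-2
convolutions halve the resolution to 1/16, a decoder with nearest-neighbor
upsampling and skip concatenations restores it, Leaky ReLU throughout, and
a **zero-initialized** final 2-channel layer — an untrained network is
exactly the identity transform. Training minimizes
`-similarity(warp(moving), fixed) + lambda * mean(|grad field|^2)` with
Adam (lr 1e-4, batch 8), similarity = local NCC, `lambda = 0.01` by
default. Larger `lambda` measurably shrinks the learned fields (asserted as
a 3-point sweep in the acceptance suite).

## Difference mapping

On unit-range aligned crops, `D = Img2 * |Img2 - Img1|`: the absolute
temporal difference weighted by the post intensity, so change that is
bright *now* is emphasized and regions that were bright only before are
suppressed. The enhancement `f_k(D) = 2/(1 + exp(-k D)) - 1` (k = 6 for
"nonlinear-1", k = 12 for "nonlinear-2") is a sigmoid restricted to its
positive range: zero stays zero, larger differences are amplified but never
reach 1. The highlighted image `Imgnew = Img2 + D*` can exceed 1; it is
clipped to [0, 1] and the clipped fraction is reported, because `Imgnew`
feeds the classifier and must remain a valid image. The heat-map palette is
a strictly monotone blue-to-red map (not jet, whose dark-end rolloffs break
the ordering between difference magnitude and redness); overlays blend with
the raw post image.

## Detector

A one-stage anchor-based detector: reduced residual backbone (stem plus
three stride-2 residual stages, stride 16), shared convolutional class/box
subnets, 9 anchors per cell (scales `2^{0,1/3,2/3}`, aspect ratios
0.5/1/2), focal loss (alpha 0.25, gamma 2) with assignment thresholds
0.5/0.4, smooth-L1 box regression (weight 2), Adam lr 1e-4 with plateau
decay (factor 0.1, patience 3), batch 1. This is a desk-scale profile: one
pyramid level instead of P3–P7, because a single large lung box does not
need a multi-scale pyramid and a CPU must train it in minutes. At
inference, the returned box is the score-weighted average of all candidate
boxes overlapping the top detection ("box voting"), which averages out
per-anchor regression noise and raises mean IoU by several points on
phantoms.

## Classifiers

The trunk is densely connected: four dense blocks (each layer convolves the
concatenation of everything before it) with three 1x1-conv + average-pool
transitions, then a 1x1 reduction to 16 channels, global average pooling to
a 16-vector, and a fully connected sigmoid head with one output per
disease class — multi-label, so no softmax coupling, and per-class binary
cross-entropy as the loss. Batch normalization is omitted at this scale
(batch size 2 makes its statistics meaningless).

The dual-input variant processes the difference image with two
convolutions, a max-pool and global average pooling into one weight per
stem channel, then rescales the post-image stem features by `(1 + w)`
("operation block") before the shared trunk. With `w = 0` the block is the
identity: building the dual network with `weight_init = "zero"` and shared
weights reproduces the single-input network bit-for-bit, which the tests
assert. For *training*, the secondary path's final layer is randomly
initialized — with zero init it receives no gradient signal at this scale
and never leaves zero.

**Desk-scale schedule.** The full-scale schedule (Adam lr 1e-4, plateau
0.1/3, 40 epochs, batch 2) remains the configuration default. The tests
train at 32x32 with lr 1e-3 and patience 10: with 160 training pairs the
loss surface has a wide trivial plateau (predict the class prior), lr 1e-4
cannot escape it within 40 epochs, and patience 3 then decays the learning
rate to nothing while still on the plateau. Raising the learning rate and
the patience for a ~100x smaller model/input is an ordinary scaling
adjustment, decided from optimization diagnostics, and is confined to the
desk profile.

## Evaluation and cross-validation

Boxes use 0-based half-open coordinates, so areas and IoU are exact pixel
counts (the classic off-by-one failure is asserted against in the tests).
PSNR uses the declared depth's peak and refuses mixed depths; SSIM uses the
standard 11x11 Gaussian window (sigma 1.5, K1 = 0.01, K2 = 0.03) averaged
over the fully-windowed region; NCC is the global Pearson coefficient; AUC
is the midrank Mann–Whitney statistic, with single-valued classes excluded
from the macro mean with a warning. `kfold()` produces shuffled folds whose
sizes differ by at most one, deterministic under a seed.

## Numerical and degenerate-input choices

* Otsu on a constant image, NCC of a constant image, boxes with zero area
  and empty masks are errors, not silent values.
* Histogram matching quantizes through 256 bins (outputs are multiples of
  1/255 at unit depth); self-matching is identity up to one grey level and
  repeated matching is idempotent at the same tolerance.
* Local NCC skips windows with variance below 1e-12 in either image and
  its value is the signed squared correlation, so anti-correlation maps to
  -1.
* The identity end-to-end check is asserted at max abs difference 0.01:
  8-bit PNG quantization plus a near-zero (not bit-zero) registration
  field on identical inputs.
* Float32 is the on-disk field/weight precision for fields
  (`write_field()`), float64 for model weights (`save_model()`).

## Known limitations

* The phantom is geometric; none of the networks trained on it transfer to
  real radiographs, and absolute metric values on phantoms are not
  comparable to values reported on clinical data.
* The detector implements one pyramid level; images whose lung field is a
  small fraction of the frame would need the full multi-level profile.
* The classical registration metric ascent is local; displacements beyond
  the coarse level's capture range (roughly 15 px at the 512 scale) are
  not recovered.
* MI-driven classical registration uses an approximate histogram gradient
  and is noticeably noisier than the local-correlation default.
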