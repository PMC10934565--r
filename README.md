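# lungdiff

Longitudinal chest-radiograph comparison in R: given two radiographs of the
same subject taken at different times, `lungdiff` segments the lung fields,
deformably registers the earlier image onto the later one, computes an
enhanced temporal difference map with heat-map rendering, and classifies
thoracic disease from the post image with or without the difference
information. It is aimed at researchers in medical image analysis who want
a fully tested, CPU-only reference implementation of this four-stage
pipeline, exercised end to end on synthetic phantoms with exact ground
truth.

## The method

With unit-range, registered images `Img1` (earlier, *working/moving*) and
`Img2` (later, *reference/fixed*):

* **Difference image** `D = Img2 ⊙ |Img2 − Img1|` — the absolute temporal
  change weighted by the post-image intensity, so new bright findings are
  emphasized and vanished bright structure is suppressed.
* **Nonlinear enhancement** `D* = 2 / (1 + e^(−k·D)) − 1` with `k = 6`
  ("nonlinear-1") or `k = 12` ("nonlinear-2") — a sigmoid restricted to its
  positive range: near-zero differences stay near zero, larger ones are
  amplified but never reach 1.
* **Highlighted image** `Imgnew = clip(Img2 + D*, 0, 1)`, plus a blue→red
  heat-map overlay (blue = small change, red = large).

Upstream of this, lung fields are found either by a classical chain
(CLAHE → Otsu → border-component removal → morphological open/close →
below-mean-area removal → bounding box + allowance) or by a one-stage
anchor-based detector (residual backbone, focal loss, smooth-L1 box
regression, NMS); registration is either dense displacement-field gradient
ascent on windowed normalized cross-correlation (or joint-histogram mutual
information) or a U-Net that predicts the field in a single pass, trained
unsupervised with `−similarity + λ‖∇φ‖²`. Classification uses a densely
connected trunk with a 16-channel final block, global average pooling and a
12-way multi-label sigmoid head; the dual-input variant converts the
difference image into per-channel weights `w` and rescales the post-image
stem features by `(1 + w)` before the shared trunk.

Everything — including the convolutional networks and their training — runs
on plain CPU R (compiled kernels via Rcpp/RcppArmadillo); no GPU or Python
runtime is required.

## Worked example

```r
library(lungdiff)

# 1. a synthetic patient: pre/post pair with one new 7-px lesion
spec <- phantom_spec(
  image_size  = 256,
  new_lesions = list(list(center = c(0.45, 0.62), radius = 7, delta = 0.25)),
  deformation = list(spacing = 32, max_mag = 3),
  global_shift = c(2, -1), gain = 1.03, offset = -0.02, seed = 42)
pair <- generate_pair(spec)

# 2. lung-field segmentation (classical chain)
cfg <- classical_config(work_size = 256, allowance = 5, morph_radius = 2)
box <- segment_classical(pair$post, cfg)$box
print(box)
#> <lung_box rows [49,207) cols [39,219) area 28440 px>
iou(box, pair$truth$lung_box)
#> [1] 0.926

# 3. registration of the pre image onto the post image
reg <- register_pair(pair$pre, pair$post, method = "classical",
                     classical_register_config(iterations = 40))
print(reg)
#> <registration_result classical: PSNR 21.80->30.61 dB,
#>  SSIM 0.6448->0.8638, NCC 0.9499->0.9935>

# 4. difference map and highlighted image
dm <- difference_map(unclass(reg$warped), unclass(pair$post), "nonlinear-1")
hl <- highlight(pair$post, dm$D_star)
hl$clip_frac
#> [1] 0.001098633
```

The segmentation box overlaps the ground-truth lung box at IoU 0.93; the
registration improves all three similarity indices (PSNR +8.8 dB, SSIM
+0.22, NCC +0.044), and about 0.1 % of pixels clip when the enhanced
difference is added back onto the post image. The new lesion dominates the
hottest percentile of `D*` (23 % of the top-1 % pixels fall inside the
true 7-px lesion mask in this example; the rest trace residual alignment
edges).

## Command line

Every stage is also a CLI subcommand (see `inst/cli/lungdiff`):

```sh
lungdiff simulate --out-dir data/ --n-pairs 10 --seed 1
lungdiff segment  --method classical --in data/pair001_post.png --out-box boxes.csv
lungdiff register --method classical --pre a.png --post b.png \
                  --out-warped w.png --out-field f.f32 --report metrics.json
lungdiff compare  --pre w.png --post b.png --mode nl1 \
                  --out-diff d.png --out-overlay o.png
lungdiff classify --dir data/ --arch dual --input-mode diff-linear \
                  --out-preds preds.csv --out-auc auc.json
lungdiff evaluate --pred boxes.csv --truth data/boxes.csv --out report.json
lungdiff run      --pre a.png --post b.png --out-dir out/
```

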