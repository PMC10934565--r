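# Evaluation metrics (IoU, detection rate, PSNR, SSIM, NCC, AUC) and the
# k-fold cross-validation plan.

#' Axis-aligned lung bounding box
#'
#' Boxes use 0-based, half-open pixel coordinates: rows `[top, bottom)`,
#' columns `[left, right)`, so the area is `(bottom - top) * (right - left)`
#' pixels.
#'
#' @param top,bottom,left,right integer pixel bounds.
#' @param allowance margin (pixels) already included in the bounds; kept for
#'   bookkeeping.
#' @return an object of class `lung_box`.
#' @export
lung_box <- function(top, bottom, left, right, allowance = 0) {
  if (!(top < bottom && left < right))
    stopf("degenerate box: need top < bottom and left < right")
  structure(list(top = as.numeric(top), bottom = as.numeric(bottom),
                 left = as.numeric(left), right = as.numeric(right),
                 allowance = allowance),
            class = "lung_box")
}

#' @export
print.lung_box <- function(x, ...) {
  cat(sprintf("<lung_box rows [%g,%g) cols [%g,%g) area %g px>\n",
              x$top, x$bottom, x$left, x$right, box_area(x)))
  invisible(x)
}

box_area <- function(b) (b$bottom - b$top) * (b$right - b$left)

#' Rescale a box between image resolutions
#'
#' Maps half-open box coordinates from one square image scale to another
#' (e.g. 512-scale detection back to a 1024 original). With integer scale
#' ratios the mapping round-trips exactly.
#'
#' @param box a [lung_box()].
#' @param from,to source and target image sizes (scalar or 2-vector rows,cols).
#' @export
box_rescale <- function(box, from, to) {
  from <- rep(from, length.out = 2); to <- rep(to, length.out = 2)
  fr <- to[1] / from[1]; fc <- to[2] / from[2]
  lung_box(box$top * fr, box$bottom * fr, box$left * fc, box$right * fc,
           allowance = box$allowance * fr)
}

#' Intersection over union of two boxes
#'
#' @param a,b [lung_box()] objects.
#' @return scalar in \[0, 1\].
#' @export
iou <- function(a, b) {
  if (box_area(a) <= 0 || box_area(b) <= 0) stopf("zero-area box")
  ih <- min(a$bottom, b$bottom) - max(a$top, b$top)
  iw <- min(a$right, b$right) - max(a$left, b$left)
  inter <- max(0, ih) * max(0, iw)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Detection rate at an IoU threshold
#'
#' @param ious numeric vector of per-image IoU values.
#' @param threshold IoU cutoff (default 0.7).
#' @return percentage in \[0, 100\].
#' @export
detection_rate <- function(ious, threshold = 0.7) {
  if (length(ious) == 0) stopf("empty IoU list")
  100 * mean(ious >= threshold)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB. Identical images return `Inf`.
#'
#' @param a,b images of equal size and depth.
#' @param peak maximum possible value; defaults to the declared depth
#'   (255 for 8-bit, 1 for unit). Mismatched depths are an error.
#' @export
psnr <- function(a, b, peak = NULL) {
  if (!all(dim(a) == dim(b))) stopf("psnr: shape mismatch")
  da <- img_depth(a); db <- img_depth(b)
  if (da != db) stopf("psnr: depth mismatch (%s vs %s); rescale explicitly", da, db)
  if (is.null(peak)) peak <- if (da == "unit") 1 else 255
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5) and stabilizers
#' `C1 = (K1 peak)^2`, `C2 = (K2 peak)^2` with K1 = 0.01, K2 = 0.03; the mean
#' is taken over the valid (fully-windowed) region.
#'
#' @param a,b images of equal size and depth.
#' @param peak dynamic range; defaults from depth.
#' @param sigma,win Gaussian window parameters.
#' @export
ssim <- function(a, b, peak = NULL, sigma = 1.5, win = 11) {
  if (!all(dim(a) == dim(b))) stopf("ssim: shape mismatch")
  da <- img_depth(a); db <- img_depth(b)
  if (da != db) stopf("ssim: depth mismatch")
  if (is.null(peak)) peak <- if (da == "unit") 1 else 255
  if (any(dim(a) < win)) stopf("ssim: image smaller than window")
  rad <- (win - 1) / 2
  k <- exp(-0.5 * ((-rad):rad)^2 / sigma^2); k <- k / sum(k)
  A <- unclass_img(a) + 0.0; B <- unclass_img(b) + 0.0
  mu_a <- cpp_sepconv_valid(A, k); mu_b <- cpp_sepconv_valid(B, k)
  saa <- cpp_sepconv_valid(A * A, k) - mu_a^2
  sbb <- cpp_sepconv_valid(B * B, k) - mu_b^2
  sab <- cpp_sepconv_valid(A * B, k) - mu_a * mu_b
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  mean(s)
}

#' Pearson correlation of two images
#'
#' @param a,b images of equal size; both must be non-constant.
#' @export
ncc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stopf("ncc: shape mismatch")
  av <- as.numeric(a); bv <- as.numeric(b)
  if (sd(av) == 0 || sd(bv) == 0) stopf("ncc undefined for a constant image")
  stats::cor(av, bv)
}

#' k-fold cross-validation plan
#'
#' Shuffled partition of `n_items` into `k` folds whose sizes differ by at
#' most one; deterministic under `seed`.
#'
#' @param n_items number of items.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return object of class `fold_plan` with `$assignment` (fold id per item)
#'   and `$folds(i)` accessor returning `list(train, test)` index vectors.
#' @export
kfold <- function(n_items, k = 5, seed = 1) {
  if (n_items < k) stopf("n_items < k")
  perm <- with_seed(seed, sample.int(n_items))
  sizes <- rep(n_items %/% k, k) + c(rep(1, n_items %% k), rep(0, k - n_items %% k))
  assignment <- integer(n_items)
  assignment[perm] <- rep(seq_len(k), times = sizes)
  plan <- list(n_items = n_items, k = k, seed = seed, assignment = assignment)
  plan$folds <- function(i) {
    test <- which(assignment == i)
    list(train = setdiff(seq_len(n_items), test), test = test)
  }
  structure(plan, class = "fold_plan")
}

#' ROC AUC from scores and binary labels
#'
#' Rank statistic (Mann-Whitney) with midrank tie handling.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector.
#' @return AUC in \[0, 1\], or `NA` (with a warning) if only one class is
#'   present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
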