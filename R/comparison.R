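# Difference-image computation and display: D = Img2 * |Img2 - Img1| on
# registered unit-range crops, optional sigmoid-style enhancement
# f_k(D) = 2 / (1 + exp(-k D)) - 1 with k = 6 ("nonlinear-1") or k = 12
# ("nonlinear-2"), the highlighted image Imgnew = clip(Img2 + D*, 0, 1), and
# a blue-to-red heat-map overlay.

#' Post-weighted absolute difference image
#'
#' `D = Img2 * |Img2 - Img1|` elementwise: the absolute temporal difference
#' weighted by the post-image intensity, which emphasizes changes that are
#' bright in the later image and suppresses regions that were bright only in
#' the earlier one.
#'
#' @param img1_aligned pre-image already registered to the post-image, unit
#'   range.
#' @param img2 post-image, unit range.
#' @return matrix `D` in \[0, 1\].
#' @export
difference_image <- function(img1_aligned, img2) {
  if (!all(dim(img1_aligned) == dim(img2))) stopf("shape mismatch")
  a <- unclass_img(img1_aligned); b <- unclass_img(img2)
  if (min(a) < -1e-9 || max(a) > 1 + 1e-9 || min(b) < -1e-9 || max(b) > 1 + 1e-9)
    stopf("difference_image expects unit-range inputs")
  b * abs(b - a)
}

#' Nonlinear difference enhancement
#'
#' Applies `f_k(D) = 2 / (1 + exp(-k D)) - 1`, a sigmoid squashed to the
#' positive range: values near zero stay near zero while larger differences
#' are amplified without exceeding 1.
#'
#' @param D difference image in \[0, 1\].
#' @param mode `"linear"` (identity), `"nonlinear-1"` (k = 6) or
#'   `"nonlinear-2"` (k = 12).
#' @return enhanced map `D*`.
#' @export
nonlinear_transform <- function(D, mode = c("linear", "nonlinear-1", "nonlinear-2")) {
  mode <- match.arg(mode)
  k <- switch(mode, "linear" = return(D), "nonlinear-1" = 6, "nonlinear-2" = 12)
  2 / (1 + exp(-k * D)) - 1
}

#' Difference map for a registered pair
#'
#' Convenience wrapper returning `D`, `D*` and the display mode.
#'
#' @inheritParams difference_image
#' @inheritParams nonlinear_transform
#' @export
difference_map <- function(img1_aligned, img2,
                           mode = c("linear", "nonlinear-1", "nonlinear-2")) {
  mode <- match.arg(mode)
  D <- difference_image(img1_aligned, img2)
  structure(list(D = D, D_star = nonlinear_transform(D, mode), mode = mode),
            class = "difference_map")
}

#' Highlighted image
#'
#' `Imgnew = Img2 + D*`, clipped to \[0, 1\]; the fraction of clipped pixels
#' is recorded in the `clip_frac` attribute.
#'
#' @param img2 post-image, unit range.
#' @param D_star enhanced difference map.
#' @return list `(imgnew, clip_frac)`.
#' @export
highlight <- function(img2, D_star) {
  if (!all(dim(img2) == dim(D_star))) stopf("shape mismatch")
  raw <- unclass_img(img2) + D_star
  clip_frac <- mean(raw > 1)
  list(imgnew = clamp01(raw), clip_frac = clip_frac)
}

# Blue -> green -> red diverging map; the red-minus-blue balance grows
# strictly monotonically with the input (unlike jet, which rolls off at the
# dark ends), so ordering of differences is preserved in hue.
heat_colors <- function(x) {
  x <- clamp01(x)
  cbind(x, 1 - abs(2 * x - 1), 1 - x)
}

#' Heat-map overlay of a difference map
#'
#' Maps `D*` through a blue-to-red colormap (low = blue, high = red) and
#' alpha-blends it over the post-image.
#'
#' @param D_star enhanced difference map in \[0, 1).
#' @param img2 post-image, unit range.
#' @param blend overlay opacity in \[0, 1\]; 0 returns the grayscale image
#'   replicated to RGB.
#' @return array `(rows, cols, 3)` in \[0, 1\].
#' @export
render_heatmap <- function(D_star, img2, blend = 0.5) {
  if (!all(dim(D_star) == dim(img2))) stopf("shape mismatch")
  cols <- heat_colors(as.numeric(D_star))
  out <- array(0, c(nrow(img2), ncol(img2), 3))
  g <- unclass_img(img2)
  for (ch in 1:3)
    out[, , ch] <- (1 - blend) * g + blend * matrix(cols[, ch], nrow(img2))
  out
}

#' Color level bar for heat-map figures
#'
#' A vertical strip running the full colormap from 0 (bottom, blue) to 1
#' (top, red), for display beside a heat-map overlay.
#'
#' @param height bar height in pixels.
#' @param width bar width in pixels.
#' @return RGB array `(height, width, 3)`.
#' @export
heat_level_bar <- function(height = 256, width = 24) {
  lv <- seq(1, 0, length.out = height)
  cols <- heat_colors(lv)
  out <- array(0, c(height, width, 3))
  for (ch in 1:3) out[, , ch] <- matrix(cols[, ch], height, width)
  out
}
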