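# Shared intensity operations: depth handling, CLAHE, Otsu binarization,
# histogram matching, resizing and PNG I/O.
#
# Two pixel depths are supported and carried as the "depth" attribute of a
# plain matrix:
#   "unit" -- doubles in [0, 1]
#   "8bit" -- integers in [0, 255]
# Conversion is exact division/multiplication by 255; unit -> 8bit rounds to
# the nearest level.

#' Construct a grayscale image
#'
#' Wraps a numeric matrix as a grayscale image with a declared depth.
#'
#' @param pixels numeric matrix (rows x cols).
#' @param depth `"unit"` for values in \[0, 1\] or `"8bit"` for \[0, 255\].
#' @return the matrix with a `depth` attribute set.
#' @export
gray_image <- function(pixels, depth = c("unit", "8bit")) {
  depth <- match.arg(depth)
  if (!is.matrix(pixels)) stopf("pixels must be a matrix")
  rng <- range(pixels)
  lim <- if (depth == "unit") c(0, 1) else c(0, 255)
  if (rng[1] < lim[1] - 1e-9 || rng[2] > lim[2] + 1e-9)
    stopf("pixel values outside declared %s range", depth)
  attr(pixels, "depth") <- depth
  pixels
}

img_depth <- function(img) {
  d <- attr(img, "depth")
  if (!is.null(d)) return(d)
  if (max(img) <= 1 + 1e-12) "unit" else "8bit"
}

#' @rdname gray_image
#' @param img grayscale image matrix.
#' @export
to_unit <- function(img) {
  if (img_depth(img) == "unit") return(gray_image(unclass_img(img), "unit"))
  gray_image(unclass_img(img) / 255, "unit")
}

#' @rdname gray_image
#' @export
to_8bit <- function(img) {
  if (img_depth(img) == "8bit") {
    m <- round(unclass_img(img))
    return(gray_image(m, "8bit"))
  }
  gray_image(round(unclass_img(img) * 255), "8bit")
}

unclass_img <- function(img) {
  attr(img, "depth") <- NULL
  img
}

#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile histogram equalization with histogram bins clipped at
#' `clip_limit` times the mean bin height (excess redistributed uniformly)
#' and bilinear blending of the tile mappings across the image. Operates on
#' the 8-bit representation; a unit-depth input is converted in and back out.
#'
#' @param img grayscale image (matrix; unit or 8-bit depth).
#' @param clip_limit positive clip factor (multiples of the uniform bin
#'   height). Default 2.
#' @param tile_grid integer 2-vector, tiles along rows and columns. Default
#'   `c(8, 8)`.
#' @return enhanced image at the input depth.
#' @export
clahe <- function(img, clip_limit = 2, tile_grid = c(8, 8)) {
  if (clip_limit <= 0) stopf("clip_limit must be positive")
  depth <- img_depth(img)
  m8 <- to_8bit(img)
  if (nrow(m8) < tile_grid[1] || ncol(m8) < tile_grid[2])
    stopf("CLAHE tile grid (%d x %d) larger than image", tile_grid[1], tile_grid[2])
  out <- cpp_clahe(matrix(as.integer(m8), nrow(m8)), as.integer(tile_grid[1]),
                   as.integer(tile_grid[2]), clip_limit)
  out <- gray_image(out + 0.0, "8bit")
  if (depth == "unit") to_unit(out) else out
}

#' Otsu threshold and binarization
#'
#' Exhaustive search over the 256 candidate 8-bit levels for the threshold
#' maximizing between-class variance. Pixels strictly above the threshold map
#' to 255, the rest to 0.
#'
#' @param img grayscale image.
#' @return list with `threshold` (on the input depth scale) and `mask`
#'   (integer matrix of 0/255).
#' @export
otsu_binarize <- function(img) {
  depth <- img_depth(img)
  m8 <- as.integer(to_8bit(img))
  h <- tabulate(m8 + 1L, nbins = 256L)
  if (sum(h > 0) < 2) stopf("Otsu threshold undefined for a constant image")
  p <- h / sum(h)
  omega <- cumsum(p)              # class-0 probability for threshold t = level
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  t8 <- which.max(sigma_b) - 1L   # threshold level; class 0 = levels <= t8
  mask <- matrix(ifelse(matrix(m8, nrow(img)) > t8, 255L, 0L), nrow(img))
  thr <- if (depth == "unit") t8 / 255 else t8
  list(threshold = thr, mask = mask)
}

#' Histogram matching
#'
#' Monotone 256-bin quantile mapping of the working image's intensities so
#' that its cumulative distribution approximates the reference's. Both images
#' must share depth; geometry is unchanged. Output is quantized to 8-bit
#' levels (at unit depth, multiples of 1/255) -- the documented dialect.
#'
#' @param working image to be remapped.
#' @param reference image supplying the target distribution.
#' @return remapped working image at the input depth.
#' @export
histogram_match <- function(working, reference) {
  dw <- img_depth(working); dr <- img_depth(reference)
  if (dw != dr) stopf("histogram_match: depth mismatch (%s vs %s)", dw, dr)
  w8 <- as.integer(to_8bit(working))
  r8 <- as.integer(to_8bit(reference))
  cdf_w <- cumsum(tabulate(w8 + 1L, 256L)) / length(w8)
  cdf_r <- cumsum(tabulate(r8 + 1L, 256L)) / length(r8)
  # smallest reference level whose CDF reaches the working CDF
  lut <- findInterval(cdf_w, cdf_r, left.open = TRUE)  # 0..255, monotone
  lut <- pmin(lut, 255L)
  out <- matrix(lut[w8 + 1L] + 0.0, nrow(working))
  out <- gray_image(out, "8bit")
  if (dw == "unit") to_unit(out) else out
}

#' Bilinear resize
#'
#' @param img grayscale image.
#' @param size integer 2-vector `(rows, cols)`.
#' @return resized image, same depth.
#' @export
resize_to <- function(img, size) {
  if (any(size < 1)) stopf("target size must be positive")
  depth <- img_depth(img)
  if (all(dim(img) == size)) return(gray_image(unclass_img(img) + 0.0, depth))
  gray_image(cpp_resize_bilinear(unclass_img(img) + 0.0, size[1], size[2]), depth)
}

#' Nearest-neighbour mask resize (keeps masks binary)
#'
#' @param mask integer matrix.
#' @param size integer 2-vector `(rows, cols)`.
#' @export
resize_mask <- function(mask, size) {
  cpp_resize_nearest(matrix(as.integer(mask), nrow(mask)), size[1], size[2])
}

#' Read a grayscale PNG
#'
#' 8- or 16-bit grayscale PNG; 16-bit values are rescaled by max-range
#' division. RGB inputs are averaged to gray.
#'
#' @param path file path.
#' @return unit-depth image matrix.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  gray_image(clamp01(a), "unit")
}

#' Write a grayscale PNG
#'
#' @param img image matrix (any depth; converted to unit).
#' @param path output file.
#' @export
write_gray_png <- function(img, path) {
  u <- clamp01(unclass_img(to_unit(img)))
  png::writePNG(u, path)
  invisible(path)
}
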