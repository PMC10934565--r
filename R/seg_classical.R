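# Traditional lung-field segmentation: CLAHE enhancement -> Otsu
# binarization -> removal of border-touching (background) components ->
# morphological open/close -> removal of below-mean-area components ->
# bounding box with allowance.

#' Connected-component labeling
#'
#' Maximal connected foreground regions under 4- or 8-connectivity; labels
#' are assigned in raster order of each component's first pixel, so the
#' labeling is deterministic.
#'
#' @param mask binary matrix (0/1 or 0/255).
#' @param connectivity 4 or 8 (default 8).
#' @return list with `labels` (integer matrix, 0 = background), `n`
#'   components and `areas` (named pixel counts).
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  m <- matrix(as.integer(mask != 0), nrow(mask))
  lab <- cpp_label_components(m, as.integer(connectivity))
  n <- max(lab)
  areas <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  list(labels = lab, n = n, areas = areas)
}

#' Remove background-related components
#'
#' Deletes every component that touches the image border (the operational
#' definition of "background-related" used by the classical chain).
#'
#' @param cs a component set from [label_components()].
#' @return binary matrix with border-touching components removed.
#' @export
remove_background_components <- function(cs) {
  lab <- cs$labels
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border <- border[border > 0]
  out <- matrix(as.integer(lab > 0 & !(lab %in% border)), nr)
  out
}

#' Morphological opening then closing with a disk
#'
#' @param mask binary matrix.
#' @param radius disk radius in pixels.
#' @return smoothed binary matrix.
#' @export
morph_open_close <- function(mask, radius = 3) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  if (radius < 1) return(m)
  opened <- cpp_dilate_disk(cpp_erode_disk(m, radius), radius)
  cpp_erode_disk(cpp_dilate_disk(opened, radius), radius)
}

#' Keep components with at-least-mean area
#'
#' Computes the mean component area and keeps exactly the components whose
#' area is greater than or equal to it (a single component is always kept).
#'
#' @param cs component set from [label_components()].
#' @return binary matrix of surviving components.
#' @export
filter_small_components <- function(cs) {
  if (cs$n == 0) stopf("no components to filter")
  keep <- which(cs$areas >= mean(cs$areas))
  matrix(as.integer(cs$labels %in% keep), nrow(cs$labels))
}

#' Tight bounding box of a mask plus allowance
#'
#' @param mask binary matrix.
#' @param allowance margin in pixels added on every side, clipped to the
#'   image bounds.
#' @return a [lung_box()] in 0-based half-open coordinates.
#' @export
lung_box_from_mask <- function(mask, allowance = 0) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("empty mask: no foreground pixels")
  top <- min(idx[, 1]) - 1; bottom <- max(idx[, 1])       # half-open
  left <- min(idx[, 2]) - 1; right <- max(idx[, 2])
  lung_box(max(0, top - allowance), min(nrow(mask), bottom + allowance),
           max(0, left - allowance), min(ncol(mask), right + allowance),
           allowance = allowance)
}

#' Classical segmentation configuration
#'
#' @param clip_limit,tile_grid CLAHE parameters.
#' @param connectivity component connectivity (8).
#' @param morph_radius disk radius at the working scale (3 at 512).
#' @param allowance box margin at the working scale (10 at 512).
#' @param work_size processing resolution (512); detections are mapped back
#'   to the input resolution.
#' @param polarity `"auto"` detects whether the lungs fall in the brighter or
#'   darker Otsu class by comparing class means with the border mean;
#'   `"bright"`/`"dark"` force it.
#' @export
classical_config <- function(clip_limit = 2, tile_grid = c(8, 8),
                             connectivity = 8, morph_radius = 3,
                             allowance = 10, work_size = 512,
                             polarity = c("auto", "dark", "bright")) {
  list(clip_limit = clip_limit, tile_grid = tile_grid,
       connectivity = connectivity, morph_radius = morph_radius,
       allowance = allowance, work_size = work_size,
       polarity = match.arg(polarity))
}

#' Classical lung-field segmentation
#'
#' Runs the full traditional chain on a radiograph and returns the lung ROI
#' box (mapped back to the input resolution) together with the final lung
#' mask at the working resolution.
#'
#' @param img grayscale image (unit or 8-bit).
#' @param config a [classical_config()].
#' @return list `(box, mask, work_size)`; `box` is a [lung_box()] at the
#'   input resolution.
#' @export
segment_classical <- function(img, config = classical_config()) {
  in_size <- dim(img)
  work <- resize_to(to_unit(img), c(config$work_size, config$work_size))
  enh <- clahe(work, config$clip_limit, config$tile_grid)
  ob <- otsu_binarize(enh)
  bright <- ob$mask != 0
  polarity <- config$polarity
  if (polarity == "auto") {
    # lungs sit in the intensity class that matches the (air) border ring
    e <- unclass_img(enh)
    nr <- nrow(e); ncol_ <- ncol(e)
    ring <- c(e[1:5, ], e[(nr - 4):nr, ], e[, 1:5], e[, (ncol_ - 4):ncol_])
    mb <- mean(e[bright]); md <- mean(e[!bright])
    polarity <- if (abs(mean(ring) - md) <= abs(mean(ring) - mb)) "dark" else "bright"
  }
  cand <- if (polarity == "dark") matrix(as.integer(!bright), nrow(ob$mask))
          else matrix(as.integer(bright), nrow(ob$mask))
  cs <- label_components(cand, config$connectivity)
  if (cs$n == 0) stopf("segmentation failed: binarization produced no components")
  interior <- remove_background_components(cs)
  smooth <- morph_open_close(interior, config$morph_radius)
  cs2 <- label_components(smooth, config$connectivity)
  if (cs2$n == 0)
    stopf("segmentation failed: no lung candidates after morphology; try a smaller morph_radius")
  lungs <- filter_small_components(cs2)
  box_work <- lung_box_from_mask(lungs, config$allowance)
  box <- box_rescale(box_work, from = config$work_size, to = in_size)
  list(box = box, mask = lungs, work_size = config$work_size)
}
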