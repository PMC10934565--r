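# Synthetic chest-radiograph phantom: two dark elliptical lung fields inside
# a bright thorax on a dark background, periodic rib bands crossing the
# lungs, optional bright lesions, smooth random deformation between the two
# time points, detector gain/offset differences and Gaussian noise.
#
# The phantom makes no anatomical claim; it provides separable structure with
# exact ground truth (lung mask, tight lung box, dense displacement field,
# lesion mask, multi-hot labels) so that every pipeline stage is testable.

#' The 12 disease classes used by the label vector
#' @export
DISEASE_CLASSES <- c("Atelectasis", "Cardiomegaly", "Effusion", "Infiltration",
                     "Mass", "Nodule", "Pneumonia", "Pneumothorax",
                     "Consolidation", "Emphysema", "Fibrosis",
                     "Pleural_Thickening")

#' Phantom specification
#'
#' All geometry defaults are fractions of the image size so that phantoms
#' render consistently at any resolution; pixel-valued arguments
#' (`lesion radius`, deformation spacing/magnitude, shift) are taken at the
#' requested `image_size`.
#'
#' @param image_size square image side in pixels (default 512).
#' @param lung_params list of two ellipse descriptors
#'   `list(center = c(row, col), semi = c(a_row, a_col), intensity)` in
#'   fractional coordinates; defaults give two lung fields.
#' @param rib_count number of rib bands (default 7).
#' @param lesion_list list of lesions `list(center = c(row, col) fractional,
#'   radius = px, delta = intensity in [0,1])` present in the image (and in
#'   both images of a pair).
#' @param new_lesions lesions added only to the post image of a pair.
#' @param distractor_list benign lesion mimics (e.g. calcified granulomas):
#'   rendered exactly like lesions, present in both images of a pair, but
#'   excluded from the lesion mask and the label vector.
#' @param noise_sigma grayscale noise std in \[0, 1\] (default 0.01).
#' @param deformation list `(spacing = control grid spacing px,
#'   max_mag = max displacement px)`; `max_mag` must stay below `spacing`.
#' @param global_shift integer `(rows, cols)` translation of the post image.
#' @param gain,offset detector intensity model of the post image
#'   (`post = gain * x + offset`).
#' @param allowance ground-truth box margin in px (default 0 = tight box).
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512,
                         lung_params = NULL,
                         rib_count = 7,
                         lesion_list = list(),
                         new_lesions = list(),
                         distractor_list = list(),
                         noise_sigma = 0.01,
                         deformation = list(spacing = 64, max_mag = 6),
                         global_shift = c(0, 0),
                         gain = 1, offset = 0,
                         allowance = 0,
                         seed = 1) {
  if (is.null(lung_params)) {
    lung_params <- list(
      list(center = c(0.52, 0.32), semi = c(0.30, 0.155), intensity = 0.30),
      list(center = c(0.52, 0.68), semi = c(0.30, 0.155), intensity = 0.30))
  }
  for (les in c(lesion_list, new_lesions, distractor_list)) {
    if (les$radius <= 0) stopf("lesion radius must be positive")
    if (!lesion_inside_lungs(les, lung_params))
      stopf("lesion at (%.2f, %.2f) lies outside the lung ellipses",
            les$center[1], les$center[2])
  }
  if (deformation$max_mag >= deformation$spacing)
    stopf("deformation max_mag must be smaller than the control-grid spacing")
  structure(list(image_size = image_size, lung_params = lung_params,
                 rib_count = rib_count, lesion_list = lesion_list,
                 new_lesions = new_lesions, distractor_list = distractor_list,
                 noise_sigma = noise_sigma,
                 deformation = deformation, global_shift = global_shift,
                 gain = gain, offset = offset, allowance = allowance,
                 seed = seed),
            class = "phantom_spec")
}

lesion_profile <- function(d, radius, taper = 1.5) {
  prof <- numeric(length(d))
  prof[d <= radius] <- 1
  edge <- d > radius & d <= radius + taper
  prof[edge] <- 0.5 * (1 + cos(pi * (d[edge] - radius) / taper))
  prof
}

lesion_inside_lungs <- function(les, lung_params) {
  for (lp in lung_params) {
    d <- ((les$center[1] - lp$center[1]) / lp$semi[1])^2 +
         ((les$center[2] - lp$center[2]) / lp$semi[2])^2
    if (d <= 1) return(TRUE)
  }
  FALSE
}

# Render the noise-free anatomy plus masks. Lesions from `lesions` (a list)
# are stamped after a light blur so the rendered mean delta matches the
# requested delta.
render_anatomy <- function(spec, lesions) {
  n <- spec$image_size
  sc <- n / 512                       # pixel-parameter scale factor
  rr <- matrix(seq_len(n), n, n) / n  # fractional row coords
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) / n
  img <- matrix(0.10, n, n)           # dark background (air)
  thorax <- ((rr - 0.55) / 0.45)^2 + ((cc - 0.50) / 0.42)^2 <= 1
  img[thorax] <- 0.70
  lung_mask <- matrix(0L, n, n)
  for (lp in spec$lung_params) {
    inside <- ((rr - lp$center[1]) / lp$semi[1])^2 +
              ((cc - lp$center[2]) / lp$semi[2])^2 <= 1
    img[inside] <- lp$intensity
    lung_mask[inside] <- 1L
  }
  # gastric air bubble: a moderate dark blob under the left hemidiaphragm,
  # standard on upright radiographs; gives the component-area filter a
  # sub-mean region to remove, as on real images
  bubble <- ((rr - 0.90) / 0.04)^2 + ((cc - 0.62) / 0.05)^2 <= 1
  img[bubble & thorax] <- 0.25
  if (spec$rib_count > 0) {
    # periodic bright bands across the thorax (and over the lungs)
    top <- 0.55 - 0.45; bot <- 0.55 + 0.45
    centers <- seq(top + 0.08, bot - 0.20, length.out = spec$rib_count)
    width <- (5 * sc) / n
    band <- Reduce(`|`, lapply(centers, function(t0) abs(rr - t0) <= width / 2))
    img[band & thorax] <- img[band & thorax] + 0.13
  }
  img <- cpp_gaussian_blur(img, 1.5 * sc)
  if (length(spec$distractor_list %||% list()) > 0)
    img <- img + render_lesions_only(spec, spec$distractor_list)$img
  lesion_mask <- matrix(0L, n, n)
  for (les in lesions) {
    d2 <- (matrix(seq_len(n), n, n) - les$center[1] * n)^2 +
          (matrix(seq_len(n), n, n, byrow = TRUE) - les$center[2] * n)^2
    d <- sqrt(d2)
    # full delta inside the mask radius, cosine taper just outside it, so
    # the mean rendered delta over the lesion mask equals the requested one
    prof <- lesion_profile(d, les$radius)
    img <- img + les$delta * matrix(prof, n, n)
    lesion_mask[d <= les$radius] <- 1L
  }
  lesion_mask <- lesion_mask * lung_mask   # lesions live inside lungs
  list(img = img, lung_mask = lung_mask, lesion_mask = lesion_mask)
}

labels_from_lesions <- function(lesions) {
  lab <- setNames(integer(length(DISEASE_CLASSES)), DISEASE_CLASSES)
  if (length(lesions) > 0) lab["Nodule"] <- 1L
  lab
}

add_noise_clip <- function(img, sigma) {
  if (sigma > 0) img <- img + matrix(rnorm(length(img), 0, sigma), nrow(img))
  clipped <- mean(img < 0 | img > 1)
  out <- clamp01(img)
  attr(out, "clip_frac") <- clipped
  out
}

#' Generate a single phantom radiograph with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return `list(image, truth)`; `image` is a unit-range matrix with a
#'   `clip_frac` attribute; `truth` holds `lung_mask`, `lung_box`,
#'   `lesion_mask` and the multi-hot `labels`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    an <- render_anatomy(spec, spec$lesion_list)
    img <- add_noise_clip(an$img, spec$noise_sigma)
    truth <- list(lung_mask = an$lung_mask,
                  lung_box = lung_box_from_mask(an$lung_mask, spec$allowance),
                  lesion_mask = an$lesion_mask,
                  labels = labels_from_lesions(spec$lesion_list))
    list(image = img, truth = truth)
  })
}

# Smooth random displacement field from a coarse control grid plus a global
# shift; returns list(drow, dcol) at full resolution.
sample_deformation <- function(n, spacing, max_mag, global_shift) {
  ng <- max(2L, as.integer(ceiling(n / spacing)) + 1L)
  drow <- matrix(rnorm(ng * ng), ng, ng)
  dcol <- matrix(rnorm(ng * ng), ng, ng)
  mag <- sqrt(drow^2 + dcol^2)
  s <- if (max_mag > 0 && max(mag) > 0) max_mag / max(mag) else 0
  drow <- cpp_resize_bilinear(drow * s, n, n) + global_shift[1]
  dcol <- cpp_resize_bilinear(dcol * s, n, n) + global_shift[2]
  list(drow = drow, dcol = dcol)
}

#' Generate a pre/post phantom pair with ground truth
#'
#' The post image is the pre anatomy pulled back through a smooth random
#' displacement field (plus an integer global shift), with any new lesions
#' stamped in post geometry, a detector gain/offset applied and noise added.
#' Conventions: `post(p) = gain * pre_anatomy(p + field(p)) + offset`
#' (+ lesions + noise), so warping the pre image with `truth$true_field`
#' aligns it to the post image.
#'
#' @param spec a [phantom_spec()].
#' @return `list(pre, post, truth)` where `truth` contains post-geometry
#'   `lung_mask` / `lung_box` / `lesion_mask`, pre-geometry
#'   `lung_mask_pre` / `lung_box_pre`, the dense `true_field`
#'   (`list(drow, dcol)`) and the label vector of the post image.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    an <- render_anatomy(spec, spec$lesion_list)
    field <- sample_deformation(spec$image_size, spec$deformation$spacing,
                                spec$deformation$max_mag, spec$global_shift)
    post_anat <- cpp_warp_bilinear(an$img, field$drow, field$dcol)
    # masks follow the same pull-back (nearest-neighbour to stay binary)
    warp_mask <- function(m) {
      w <- cpp_warp_bilinear(m + 0.0, field$drow, field$dcol)
      matrix(as.integer(w >= 0.5), nrow(m))
    }
    lung_post <- warp_mask(an$lung_mask)
    lesion_post <- warp_mask(an$lesion_mask)
    if (length(spec$new_lesions) > 0) {
      stamp <- render_lesions_only(spec, spec$new_lesions)
      post_anat <- post_anat + stamp$img
      lesion_post[stamp$mask > 0 & lung_post > 0] <- 1L
    }
    post_anat <- spec$gain * post_anat + spec$offset
    pre <- add_noise_clip(an$img, spec$noise_sigma)
    post <- add_noise_clip(post_anat, spec$noise_sigma)
    all_lesions <- c(spec$lesion_list, spec$new_lesions)
    truth <- list(
      lung_mask = lung_post,
      lung_box = lung_box_from_mask(lung_post, spec$allowance),
      lung_mask_pre = an$lung_mask,
      lung_box_pre = lung_box_from_mask(an$lung_mask, spec$allowance),
      lesion_mask = lesion_post,
      true_field = field,
      labels = labels_from_lesions(all_lesions))
    list(pre = pre, post = post, truth = truth)
  })
}

# Lesion stamps alone (zero background), used for post-only lesions.
render_lesions_only <- function(spec, lesions) {
  n <- spec$image_size
  img <- matrix(0, n, n)
  mask <- matrix(0L, n, n)
  for (les in lesions) {
    d <- sqrt((matrix(seq_len(n), n, n) - les$center[1] * n)^2 +
              (matrix(seq_len(n), n, n, byrow = TRUE) - les$center[2] * n)^2)
    img <- img + les$delta * matrix(lesion_profile(d, les$radius), n, n)
    mask[d <= les$radius] <- 1L
  }
  list(img = img, mask = mask)
}
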