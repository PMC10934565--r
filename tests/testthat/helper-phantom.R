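# Shared fixtures: all test data is generated in code from phantom specs.
ld <- asNamespace("lungdiff")

# n single phantoms with jittered anatomy and tight truth boxes
make_det_data <- function(n, seed0, size = 128) {
  lapply(seq_len(n), function(i) {
    sp <- ld$with_seed(seed0 + i, ld$random_pair_spec(size, 0, seed0 + i))
    p <- generate_phantom(sp)
    list(image = p$image, box = p$truth$lung_box)
  })
}

# histogram-matched moving/fixed pairs for registration training
make_reg_pairs <- function(n, seed0, size = 64) {
  lapply(seq_len(n), function(i) {
    sp <- ld$with_seed(seed0 + i, ld$random_pair_spec(size, 0, seed0 + i))
    pr <- generate_pair(sp)
    mov <- ld$unclass_img(to_unit(histogram_match(pr$pre, pr$post)))
    list(moving = mov, fixed = ld$unclass_img(pr$post))
  })
}

rand_blob <- function(lungs, sc) {
  lung <- lungs[[sample(2, 1)]]
  ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.55
  list(center = lung$center + rad * c(lung$semi[1] * cos(ang),
                                      lung$semi[2] * sin(ang)),
       radius = max(3, 7 * sc), delta = runif(1, 0.22, 0.3))
}

# Confined-signal classification task: every post image shows k lesion-like
# blobs; in positives exactly one of them is new (absent from the pre
# image), in negatives all were already present. The post image alone is
# uninformative; the difference channel isolates the new blob.
make_cls_task <- function(n, seed0, size = 32) {
  sc <- size / 512
  lapply(seq_len(n), function(i) {
    ld$with_seed(seed0 + i, {
      positive <- i %% 2 == 1
      lungs <- list(
        list(center = c(0.52, 0.32) + runif(2, -0.015, 0.015),
             semi = c(0.30, 0.155) + runif(2, -0.01, 0.01), intensity = 0.30),
        list(center = c(0.52, 0.68) + runif(2, -0.015, 0.015),
             semi = c(0.30, 0.155) + runif(2, -0.01, 0.01), intensity = 0.30))
      k <- sample(2:4, 1)
      blobs <- lapply(seq_len(k), function(j) rand_blob(lungs, sc))
      sp <- phantom_spec(image_size = size, lung_params = lungs,
                         distractor_list = if (positive) blobs[-1] else blobs,
                         new_lesions = if (positive) blobs[1] else list(),
                         noise_sigma = 0.01,
                         deformation = list(spacing = 64 * sc + 1, max_mag = 0),
                         gain = runif(1, 0.97, 1.03),
                         offset = runif(1, -0.02, 0.02),
                         seed = seed0 + i)
      pr <- generate_pair(sp)
      matched <- to_unit(histogram_match(pr$pre, pr$post))
      dm <- difference_map(ld$unclass_img(matched), ld$unclass_img(pr$post),
                           "linear")
      labels <- numeric(12); if (positive) labels[6] <- 1
      list(inputs = list(gray_image(ld$unclass_img(pr$post), "unit"),
                         gray_image(dm$D_star, "unit")),
           labels = labels)
    })
  })
}

expect_box_equal <- function(a, b, tol = 1e-9) {
  expect_equal(c(a$top, a$bottom, a$left, a$right),
               c(b$top, b$bottom, b$left, b$right), tolerance = tol)
}
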