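test_that("lesion-free noiseless phantom has empty lesion truth and is deterministic", {
  sp <- phantom_spec(image_size = 128, noise_sigma = 0, seed = 3)
  p1 <- generate_phantom(sp)
  expect_true(all(p1$truth$lesion_mask == 0))
  expect_true(all(p1$truth$labels == 0))
  p2 <- generate_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$truth$lung_mask, p2$truth$lung_mask)
  expect_true(min(p1$image) >= 0 && max(p1$image) <= 1)
  expect_equal(attr(p1$image, "clip_frac"), 0)
})

test_that("a lesion raises mean intensity inside its mask by about its delta", {
  les <- list(list(center = c(0.52, 0.32), radius = 10, delta = 0.3))
  base <- generate_phantom(phantom_spec(image_size = 128, noise_sigma = 0, seed = 4))
  with_les <- generate_phantom(phantom_spec(image_size = 128, noise_sigma = 0,
                                            lesion_list = les, seed = 4))
  m <- with_les$truth$lesion_mask > 0
  expect_gt(sum(m), 100)
  # oracle: render both and subtract
  expect_equal(mean(with_les$image[m] - base$image[m]), 0.3, tolerance = 0.02)
  expect_equal(with_les$truth$labels[["Nodule"]], 1L)
  # lesion_mask is contained in lung_mask
  expect_true(all(with_les$truth$lung_mask[m] == 1))
})

test_that("lesions outside the lung ellipses are rejected", {
  expect_error(phantom_spec(lesion_list = list(
    list(center = c(0.05, 0.05), radius = 8, delta = 0.2))), "outside")
  expect_error(phantom_spec(deformation = list(spacing = 8, max_mag = 10)),
               "spacing")
  expect_error(phantom_spec(lesion_list = list(
    list(center = c(0.52, 0.32), radius = 0, delta = 0.2))), "radius")
})

test_that("identity pair: no deformation, shift, gain/offset or noise gives pre == post", {
  sp <- phantom_spec(image_size = 96, noise_sigma = 0,
                     deformation = list(spacing = 32, max_mag = 0), seed = 5)
  pr <- generate_pair(sp)
  expect_equal(unclass(pr$pre), unclass(pr$post), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pure global shift gives a constant truth field", {
  sp <- phantom_spec(image_size = 96, noise_sigma = 0,
                     deformation = list(spacing = 32, max_mag = 0),
                     global_shift = c(3, 0), seed = 6)
  pr <- generate_pair(sp)
  expect_true(all(pr$truth$true_field$drow == 3))
  expect_true(all(pr$truth$true_field$dcol == 0))
  # and the post image is the shifted pre image in the interior
  expect_equal(pr$post[1:90, ], pr$pre[4:93, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("warping pre with the truth field explains the post image", {
  sp <- phantom_spec(image_size = 96, noise_sigma = 0.02,
                     deformation = list(spacing = 24, max_mag = 4),
                     gain = 1.04, offset = -0.02, seed = 7)
  pr <- generate_pair(sp)
  f <- pr$truth$true_field
  warped <- ld$cpp_warp_bilinear(unclass(pr$pre), f$drow, f$dcol)
  # aligned pre beats unaligned pre
  expect_gt(ncc(warped, pr$post), ncc(pr$pre, pr$post))
  # gain/offset-corrected reconstruction within noise: MSE <= 3 sigma^2
  recon <- 1.04 * warped - 0.02
  mse <- mean((recon - pr$post)^2)
  expect_lte(mse, 3 * 0.02^2)
})

test_that("truth lung box is the tight mask bounding box plus allowance", {
  sp <- phantom_spec(image_size = 128, noise_sigma = 0, allowance = 4, seed = 8)
  p <- generate_phantom(sp)
  idx <- which(p$truth$lung_mask > 0, arr.ind = TRUE)
  expect_equal(p$truth$lung_box$top, max(0, min(idx[, 1]) - 1 - 4))
  expect_equal(p$truth$lung_box$bottom, min(128, max(idx[, 1]) + 4))
})
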