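test_that("connected-component labeling honours connectivity", {
  expect_equal(label_components(matrix(0L, 5, 5))$n, 0)
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L; m[7:9, 7:9] <- 1L
  cs <- label_components(m)
  expect_equal(cs$n, 2)
  expect_equal(sort(cs$areas), c(9, 9))
  # diagonal touch: one component under 8-connectivity, two under 4
  d <- matrix(0L, 4, 4); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_equal(label_components(d, 8)$n, 1)
  expect_equal(label_components(d, 4)$n, 2)
  # labels are deterministic raster order
  expect_equal(cs$labels[2, 2], 1L)
  expect_equal(cs$labels[7, 7], 2L)
})

test_that("border-touching components are removed as background", {
  m <- matrix(0L, 10, 10)
  m[1, ] <- 1L                       # full top row
  m[5:6, 5:6] <- 1L                  # interior blob
  out <- remove_background_components(label_components(m))
  expect_true(all(out[1, ] == 0))
  expect_true(all(out[5:6, 5:6] == 1))
  # frame-shaped border component + interior blob: only the blob remains
  fr <- matrix(0L, 10, 10)
  fr[1, ] <- 1L; fr[10, ] <- 1L; fr[, 1] <- 1L; fr[, 10] <- 1L
  fr[4:6, 4:6] <- 1L
  out2 <- remove_background_components(label_components(fr))
  expect_equal(sum(out2), 9)
  expect_true(all(out2[4:6, 4:6] == 1))
})

test_that("morphological open/close behaves on canonical shapes", {
  solo <- matrix(0L, 7, 7); solo[4, 4] <- 1L
  expect_true(all(morph_open_close(solo, 1) == 0))      # opening removes it
  sq <- matrix(0L, 30, 30); sq[6:25, 6:25] <- 1L
  expect_equal(morph_open_close(sq, 1), sq)             # large square unchanged
  # one-pixel gap in a solid bar is closed
  bar <- matrix(0L, 5, 7); bar[2:4, ] <- 1L; bar[2:4, 4] <- 0L
  healed <- ld$cpp_erode_disk(ld$cpp_dilate_disk(bar, 1), 1)
  expect_true(all(healed[3, ] == 1))
  # area monotonicity: erosion and opening never grow the foreground
  set.seed(7)
  rnd <- matrix(as.integer(runif(400) > 0.6), 20)
  opened <- ld$cpp_dilate_disk(ld$cpp_erode_disk(rnd, 1), 1)
  expect_lte(sum(opened), sum(rnd))
})

test_that("mean-area component filter matches hand-computed cases", {
  # areas {100, 10}: mean 55, keep only the 100 one
  m <- matrix(0L, 30, 30)
  m[2:11, 2:11] <- 1L           # 100
  m[20:21, 20:24] <- 1L         # 10
  keep <- filter_small_components(label_components(m))
  expect_equal(sum(keep), 100)
  # areas {100, 100, 10}: mean 70, keep both 100s
  m2 <- matrix(0L, 40, 40)
  m2[2:11, 2:11] <- 1L; m2[2:11, 20:29] <- 1L; m2[30:31, 30:34] <- 1L
  keep2 <- filter_small_components(label_components(m2))
  expect_equal(sum(keep2), 200)
  # single component is always kept
  single <- matrix(0L, 10, 10); single[3:5, 3:5] <- 1L
  expect_equal(sum(filter_small_components(label_components(single))), 9)
  expect_error(filter_small_components(label_components(matrix(0L, 5, 5))),
               "no components")
})

test_that("lung box from mask: tightness, allowance, clipping", {
  m <- matrix(0L, 20, 20); m[6, 8] <- 1L
  b <- lung_box_from_mask(m, 0)
  expect_box_equal(b, lung_box(5, 6, 7, 8))
  m2 <- matrix(0L, 60, 60); m2[11:20, 21:40] <- 1L
  b2 <- lung_box_from_mask(m2, 5)
  expect_box_equal(b2, lung_box(5, 25, 15, 45))
  m3 <- matrix(0L, 10, 10); m3[1, 1] <- 1L
  b3 <- lung_box_from_mask(m3, 5)
  expect_box_equal(b3, lung_box(0, 6, 0, 6))
  expect_error(lung_box_from_mask(matrix(0L, 5, 5)), "empty")
})

test_that("classical segmentation finds the lung ROI on phantoms", {
  cfg <- classical_config(work_size = 256, allowance = 5, morph_radius = 2)
  sp <- phantom_spec(image_size = 256, noise_sigma = 0, seed = 21)
  ph <- generate_phantom(sp)
  seg <- segment_classical(ph$image, cfg)
  expect_gte(iou(seg$box, ph$truth$lung_box), 0.8)
  # determinism
  seg2 <- segment_classical(ph$image, cfg)
  expect_box_equal(seg$box, seg2$box)
  # 50 salt-noise pixels move the box by at most 2 px per side
  salted <- unclass(ph$image)
  idx <- ld$with_seed(9, sample(length(salted), 50))
  salted[idx] <- 1
  seg3 <- segment_classical(gray_image(salted, "unit"), cfg)
  expect_lte(max(abs(c(seg3$box$top - seg$box$top, seg3$box$bottom - seg$box$bottom,
                       seg3$box$left - seg$box$left, seg3$box$right - seg$box$right))), 2)
  expect_error(segment_classical(gray_image(matrix(0.5, 64, 64), "unit"), cfg),
               "constant")
})
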