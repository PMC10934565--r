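test_that("box IoU matches hand-counted cases", {
  a <- lung_box(0, 10, 0, 10)
  b <- lung_box(0, 10, 5, 15)
  expect_equal(iou(a, b), 1 / 3)                 # 50 / 150
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, lung_box(20, 30, 20, 30)), 0)
  expect_equal(iou(a, b), iou(b, a))
  expect_error(iou(a, list(top = 0, bottom = 0, left = 0, right = 5)), "box")
  # upper bound: min area / union
  expect_lte(iou(a, b), box_area(a) / (box_area(a) + box_area(b) -
                                         box_area(a)))
})

test_that("box rescaling round-trips between even scales", {
  b <- lung_box(56, 209, 42, 213)
  up <- box_rescale(b, 512, 1024)
  back <- box_rescale(up, 1024, 512)
  expect_box_equal(b, back)
})

test_that("detection rate counts correctly", {
  expect_equal(detection_rate(rep(0.9, 5), 0.7), 100)
  expect_equal(detection_rate(c(0.8, 0.6), 0.7), 50)
  expect_equal(detection_rate(c(0.2, 0.5), 0), 100)
  expect_error(detection_rate(numeric(0)), "empty")
})

test_that("PSNR closed forms", {
  a <- gray_image(matrix(c(100, 101, 100, 101), 2) + 0.0, "8bit")
  b <- gray_image(matrix(c(101, 100, 101, 100), 2) + 0.0, "8bit")  # MSE 1
  expect_equal(psnr(a, b), 20 * log10(255), tolerance = 1e-10)
  expect_equal(psnr(a, b), 48.1308, tolerance = 1e-4)
  expect_identical(psnr(a, a), Inf)
  u1 <- gray_image(matrix(0.5, 10, 10), "unit")
  u2 <- gray_image(matrix(0.5 + 0.1, 10, 10), "unit")  # MSE 0.01
  expect_equal(psnr(u1, u2), 20, tolerance = 1e-10)
  a10 <- gray_image(matrix(128, 10, 10) + 0.0, "8bit")
  expect_error(psnr(u1, a10), "depth")
  # strictly decreasing in MSE
  u3 <- gray_image(matrix(0.5 + 0.2, 10, 10), "unit")
  expect_gt(psnr(u1, u2), psnr(u1, u3))
})

test_that("SSIM identity, sensitivity and symmetry", {
  set.seed(2)
  a <- gray_image(matrix(runif(24 * 24), 24), "unit")
  expect_equal(ssim(a, a), 1)
  b <- gray_image(pmin(matrix(as.numeric(a), 24) + 0.08, 1), "unit")
  expect_lt(ssim(a, b), 1)
  c2 <- gray_image(matrix(runif(24 * 24), 24), "unit")
  expect_equal(ssim(a, c2), ssim(c2, a), tolerance = 1e-12)
})

test_that("NCC affine invariance and errors", {
  set.seed(3)
  a <- matrix(runif(100), 10)
  expect_equal(ncc(a, 2 * a + 3), 1, tolerance = 1e-12)
  expect_equal(ncc(a, -a), -1, tolerance = 1e-12)
  expect_error(ncc(a, matrix(1, 10, 10)), "constant")
  big <- matrix(runif(1e4), 100)
  expect_lte(abs(ncc(big, matrix(runif(1e4), 100))), 0.05)
})

test_that("kfold partitions evenly and deterministically", {
  plan <- kfold(2000, 5, seed = 4)
  sizes <- table(plan$assignment)
  expect_true(all(sizes == 400))
  tests <- lapply(1:5, function(i) plan$folds(i)$test)
  expect_equal(sort(unlist(tests)), 1:2000)
  expect_equal(length(unique(unlist(tests))), 2000)
  plan2 <- kfold(2000, 5, seed = 4)
  expect_identical(plan$assignment, plan2$assignment)
  # uneven n: sizes differ by at most one
  p3 <- kfold(17, 5, seed = 1)
  expect_lte(diff(range(table(p3$assignment))), 1)
  expect_error(kfold(3, 5), "n_items")
})

test_that("AUC rank statistic", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  s <- c(0.3, 0.6, 0.1, 0.8); l <- c(0, 1, 0, 1)
  expect_equal(auc_score(s, l), auc_score(log(s + 1), l))   # monotone invariance
  set.seed(5)
  big <- runif(1000); lab <- rbinom(1000, 1, 0.5)
  expect_lte(abs(auc_score(big, lab) - 0.5), 0.05)
  expect_warning(v <- auc_score(runif(5), rep(1, 5)), "one class")
  expect_true(is.na(v))
})

test_that("metrics agree with brute-force implementations on random images", {
  set.seed(6)
  for (rep in 1:3) {
    a <- matrix(runif(256), 16); b <- matrix(runif(256), 16)
    # brute-force PSNR / NCC
    mse <- sum((a - b)^2) / 256
    expect_equal(psnr(gray_image(a, "unit"), gray_image(b, "unit")),
                 10 * log10(1 / mse), tolerance = 1e-10)
    av <- as.numeric(a); bv <- as.numeric(b)
    brute_ncc <- sum((av - mean(av)) * (bv - mean(bv))) /
      sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
    expect_equal(ncc(a, b), brute_ncc, tolerance = 1e-10)
  }
})
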