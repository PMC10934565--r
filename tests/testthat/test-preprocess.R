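shannon_entropy <- function(img8) {
  p <- tabulate(as.integer(img8) + 1L, 256L)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

test_that("CLAHE: degenerate, range and error contracts", {
  const <- gray_image(matrix(128, 32, 32), "8bit")
  out <- clahe(const)
  expect_true(all(out == out[1, 1]))               # constant stays constant
  # noisy low-contrast ramp confined to [100, 130]
  set.seed(12)
  ramp <- gray_image(matrix(pmin(130, pmax(100, round(
    rep(seq(100, 130, length.out = 256), each = 256) + rnorm(256^2, 0, 3)))),
    256), "8bit")
  enh <- clahe(ramp)
  expect_gt(shannon_entropy(enh), shannon_entropy(round(ramp)))
  expect_gte(min(enh), 0); expect_lte(max(enh), 255)
  expect_error(clahe(gray_image(matrix(0.5, 4, 4), "unit"), tile_grid = c(8, 8)),
               "tile")
  # depth is preserved
  u <- clahe(gray_image(matrix(runif(64 * 64), 64), "unit"))
  expect_true(max(u) <= 1 + 1e-12)
})

test_that("Otsu maximizes between-class variance and binarizes as specified", {
  v <- c(rep(50, 60), rep(200, 40))
  img <- gray_image(matrix(v, 10), "8bit")
  r <- otsu_binarize(img)
  expect_gte(r$threshold, 50); expect_lt(r$threshold, 200)
  expect_true(all(r$mask[matrix(v, 10) == 50] == 0))
  expect_true(all(r$mask[matrix(v, 10) == 200] == 255))
  expect_true(all(r$mask %in% c(0L, 255L)))
  # exhaustive-search oracle: recompute best threshold by brute force
  h <- tabulate(as.integer(img) + 1L, 256L) / length(img)
  sb <- sapply(0:255, function(t) {
    w0 <- sum(h[1:(t + 1)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    mu0 <- sum((0:t) * h[1:(t + 1)]) / w0
    mu1 <- sum((t + 1):255 * h[(t + 2):256]) / w1
    w0 * w1 * (mu0 - mu1)^2
  })
  expect_equal(r$threshold, which.max(sb) - 1)
  # two-point distribution: between-class variance equals global variance
  x <- as.numeric(img)
  expect_equal(max(sb), mean((x - mean(x))^2), tolerance = 1e-9)
  expect_error(otsu_binarize(gray_image(matrix(7, 4, 4), "8bit")), "constant")
})

cdf_dist <- function(a, b) {
  ca <- cumsum(tabulate(as.integer(to_8bit(a)) + 1L, 256L)) / length(a)
  cb <- cumsum(tabulate(as.integer(to_8bit(b)) + 1L, 256L)) / length(b)
  max(abs(ca - cb))
}

test_that("histogram matching is monotone, contractive and idempotent", {
  set.seed(10)
  w <- gray_image(matrix(runif(900)^2, 30), "unit")
  r <- gray_image(matrix(runif(900), 30), "unit")
  m <- histogram_match(w, r)
  # self-match is identity up to one grey level
  self <- histogram_match(w, w)
  expect_lte(max(abs(self - w)), 1 / 255 + 1e-12)
  # CDF sup-distance does not increase
  expect_lte(cdf_dist(m, r), cdf_dist(w, r))
  # monotone mapping
  ow <- order(as.numeric(w))
  expect_true(all(diff(as.numeric(m)[ow]) >= -1e-12))
  # idempotence up to quantization
  m2 <- histogram_match(m, r)
  expect_lte(max(abs(m2 - m)), 1 / 255 + 1e-12)
  expect_error(histogram_match(w, to_8bit(r)), "depth")
})

test_that("resize contracts", {
  img <- gray_image(matrix(runif(64), 8), "unit")
  expect_equal(unclass(resize_to(img, c(8, 8))), unclass(img),
               tolerance = 1e-12, ignore_attr = TRUE)
  const <- gray_image(matrix(0.4, 6, 6), "unit")
  expect_true(all(abs(resize_to(const, c(3, 3)) - 0.4) < 1e-12))
  cb <- gray_image(matrix(c(0, 1, 1, 0), 2), "unit")
  expect_equal(as.numeric(resize_to(cb, c(1, 1))), 0.5)
  m <- matrix(c(1L, 0L, 0L, 1L), 2)
  expect_true(all(resize_mask(m, c(4, 4)) %in% c(0L, 1L)))
})

test_that("depth conversions are exact division/multiplication by 255", {
  img8 <- gray_image(matrix(0:255, 16), "8bit")
  u <- to_unit(img8)
  expect_equal(as.numeric(u), as.numeric(img8) / 255)
  expect_equal(as.numeric(to_8bit(u)), as.numeric(img8))
})

test_that("PNG round trip preserves 8-bit content", {
  img <- gray_image(matrix(round(runif(256) * 255) / 255, 16), "unit")
  f <- tempfile(fileext = ".png")
  write_gray_png(img, f)
  back <- read_gray_png(f)
  expect_equal(unclass(back), unclass(img), tolerance = 1 / 255,
               ignore_attr = TRUE)
  unlink(f)
})
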