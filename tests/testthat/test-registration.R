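test_that("warp: identity, integer shift, half-pixel averaging", {
  set.seed(30)
  img <- matrix(runif(15 * 15), 15)
  f0 <- ld$zero_field(15, 15)
  expect_equal(warp_image(gray_image(img, "unit"), f0), img,
               tolerance = 1e-15, ignore_attr = TRUE)
  # constant field (0, 1): shifted one column, interior exact
  f1 <- list(drow = matrix(0, 15, 15), dcol = matrix(1, 15, 15))
  w <- warp_image(gray_image(img, "unit"), f1)
  expect_equal(unclass(w)[, 1:14], img[, 2:15], tolerance = 1e-15,
               ignore_attr = TRUE)
  # half-pixel shift: neighbour averaging to 1e-12
  fh <- list(drow = matrix(0, 15, 15), dcol = matrix(0.5, 15, 15))
  wh <- warp_image(gray_image(img, "unit"), fh)
  expect_equal(unclass(wh)[, 1:14], (img[, 1:14] + img[, 2:15]) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(warp_image(gray_image(img, "unit"), ld$zero_field(4, 4)), "grid")
})

test_that("local NCC: identity, per-window affinity, sign flip", {
  set.seed(31)
  a <- matrix(runif(400), 20)
  expect_equal(local_ncc(a, a), 1, tolerance = 1e-3)
  expect_equal(local_ncc(a, 2 * a + 0.1), 1, tolerance = 1e-3)
  expect_equal(local_ncc(a, -a), -1, tolerance = 1e-3)
})

test_that("mutual information: self, symmetry, independence bound", {
  set.seed(32)
  a <- matrix(runif(1e4), 100)
  b <- matrix(runif(1e4), 100)
  # I(X;X) = H(X) for the hard-binned marginal
  cnt <- tabulate(pmin(floor(a * 16), 15) + 1, 16)
  p <- cnt / sum(cnt)
  hx <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mutual_information(a, a, bins = 16), hx, tolerance = 0.05)
  expect_equal(mutual_information(a, b, 16), mutual_information(b, a, 16),
               tolerance = 0.02)
  expect_lte(mutual_information(a, b, 16), 0.05)
  expect_gte(mutual_information(a, b, 16), 0)
})

test_that("classical registration is conservative on identical images", {
  sp <- phantom_spec(image_size = 96, noise_sigma = 0.01, seed = 33)
  ph <- generate_phantom(sp)
  res <- classical_register(ph$image, ph$image,
                            classical_register_config(iterations = 25))
  expect_lte(mean(sqrt(res$field$drow^2 + res$field$dcol^2)), 0.1)
  expect_gte(max(res$metric_trace), res$metric_trace[1])
  # best-so-far metric trace is non-decreasing
  expect_true(all(diff(cummax(res$metric_trace)) >= 0))
})

test_that("registration result carries before/after metrics and matched working image", {
  sp <- ld$with_seed(34, ld$random_pair_spec(64, 0, 34))
  pr <- generate_pair(sp)
  res <- register_pair(pr$pre, pr$post, "classical",
                       classical_register_config(iterations = 15))
  expect_named(res$metrics, c("before", "after"))
  expect_length(res$metrics$after, 3)
  # identity pair: no degradation beyond 0.01 SSIM
  resi <- register_pair(pr$post, pr$post, "classical",
                        classical_register_config(iterations = 10))
  expect_gte(resi$metrics$after["ssim"], resi$metrics$before["ssim"] - 0.01)
})

test_that("registration U-Net contracts: shape, zero-init identity, size check", {
  net <- voxelmorph_net(enc = c(4, 4, 4, 4), dec = c(4, 4, 4, 4), seed = 35)
  mov <- matrix(runif(32 * 32), 32); fix <- matrix(runif(32 * 32), 32)
  f <- net$predict(mov, fix)
  expect_equal(dim(f$drow), c(32, 32))
  expect_equal(dim(f$dcol), c(32, 32))
  # zero-initialized flow layer: untrained net is the identity transform
  expect_true(all(f$drow == 0) && all(f$dcol == 0))
  w <- ld$cpp_warp_bilinear(mov, f$drow, f$dcol)
  expect_equal(w, mov, tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(net$predict(matrix(0.1, 24, 24), matrix(0.2, 24, 24)),
               "divisible")
})

test_that("short training run reduces the registration loss reproducibly", {
  pairs <- make_reg_pairs(4, 36000, size = 32)
  net <- train_voxelmorph(pairs, net = voxelmorph_net(enc = c(4, 8, 8, 8),
                                                      dec = c(8, 8, 8, 8),
                                                      seed = 36),
                          epochs = 6, batch_size = 4, seed = 36)
  expect_lt(tail(net$history, 1), net$history[1])
  net2 <- train_voxelmorph(pairs, net = voxelmorph_net(enc = c(4, 8, 8, 8),
                                                       dec = c(8, 8, 8, 8),
                                                       seed = 36),
                           epochs = 6, batch_size = 4, seed = 36)
  expect_equal(net$history, net2$history, tolerance = 1e-12)
  expect_error(train_voxelmorph(list()), "empty")
})

test_that("displacement field container round-trips", {
  f <- list(drow = matrix(rnorm(64), 8), dcol = matrix(rnorm(64), 8))
  path <- tempfile(fileext = ".f32")
  write_field(f, path)
  back <- read_field(path)
  expect_equal(back$drow, f$drow, tolerance = 1e-6)
  expect_equal(back$dcol, f$dcol, tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})
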