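small_cfg <- function(seed = 50)
  classifier_config(input_size = 32, stem_channels = 4, growth = 3,
                    block_layers = c(1, 1, 1, 1), seed = seed)

test_that("single-input network contracts: sigmoid range, 16-d features, determinism", {
  net <- build_single_input(small_cfg())
  img <- gray_image(matrix(ld$with_seed(51, runif(32 * 32)), 32), "unit")
  p <- net$predict(img)
  expect_length(p, 12)
  expect_true(all(p > 0 & p < 1))
  # penultimate feature vector is 16-dimensional (GAP over the reduced block)
  expect_equal(nrow(net$layers$reduce$W), 16)
  expect_equal(dim(net$layers$fc$W), c(12, 16))
  expect_identical(net$predict(img), net$predict(img))
})

test_that("operation block arithmetic", {
  F1 <- array(ld$with_seed(52, rnorm(4 * 4 * 3)), c(4, 4, 3))
  expect_identical(operation_block(F1, c(0, 0, 0)), F1)
  outl <- operation_block(F1, c(1, 0, -1))
  expect_equal(outl[, , 1], 2 * F1[, , 1])
  expect_equal(outl[, , 2], F1[, , 2])
  expect_true(all(outl[, , 3] == 0))
  expect_error(operation_block(F1, c(0, 0)), "channel mismatch")
})

test_that("dual network with zeroed secondary path reproduces the single network bit-for-bit", {
  cfg <- small_cfg()
  single <- build_single_input(cfg)
  dual <- build_dual_input(cfg, share_from = single, weight_init = "zero")
  img1 <- gray_image(matrix(ld$with_seed(53, runif(32 * 32)), 32), "unit")
  img2 <- gray_image(matrix(ld$with_seed(54, runif(32 * 32)), 32), "unit")
  expect_identical(dual$forward(img1, img2), single$forward(img1))
})

test_that("gradients flow to both input paths of the dual network", {
  net <- build_dual_input(small_cfg(55))           # random weight path
  img1 <- gray_image(matrix(ld$with_seed(56, runif(32 * 32)), 32), "unit")
  img2 <- gray_image(matrix(ld$with_seed(57, runif(32 * 32)), 32), "unit")
  logits <- net$forward(img1, img2)
  r <- ld$bce_with_logits(logits, c(1, rep(0, 11)))
  net$backward(r$grad)
  expect_gt(sum(abs(net$layers$stem$dW)), 0)
  expect_gt(sum(abs(net$layers$w1$dW)), 0)
  expect_gt(sum(abs(net$layers$w2$dW)), 0)
})

test_that("multi-label heads are independent: one class's weights do not affect others", {
  net <- build_single_input(small_cfg(58))
  img <- gray_image(matrix(ld$with_seed(59, runif(32 * 32)), 32), "unit")
  p0 <- net$predict(img)
  net$layers$fc$W[3, ] <- net$layers$fc$W[3, ] + 1
  p1 <- net$predict(img)
  expect_false(p0[3] == p1[3])
  expect_identical(p0[-3], p1[-3])
})

test_that("short training reduces the loss and AUC handles degenerate classes", {
  task <- make_cls_task(16, 60000, size = 32)
  single <- lapply(task, function(d) { d$inputs <- d$inputs[2]; d })
  cfg <- small_cfg(61); cfg$lr <- 1e-3; cfg$patience <- 99
  net <- train_classifier(single, config = cfg, epochs = 5)
  expect_lt(tail(net$history, 1), net$history[1])
  w <- testthat::capture_warnings(au <- evaluate_auc(net, single))
  expect_true(any(grepl("single label", w)))   # 11 degenerate classes warn
  expect_true(is.finite(au$macro))
  expect_true(all(is.na(au$per_class[-6])))
  expect_error(train_classifier(list()), "empty")
})

test_that("classifier weights round-trip through the container", {
  cfg <- small_cfg(62)
  net <- build_single_input(cfg)
  f <- tempfile(fileext = ".bin")
  save_model(net, f)
  net2 <- build_single_input(small_cfg(63))
  load_model(net2, f)
  img <- gray_image(matrix(ld$with_seed(64, runif(32 * 32)), 32), "unit")
  expect_identical(net$forward(img), net2$forward(img))
  unlink(c(f, paste0(f, ".json")))
})
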